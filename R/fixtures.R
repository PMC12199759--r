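#' Worked-example fixture: the induced-index configuration
#'
#' An 8-node directed graph realizing the canonical induced-index example:
#' the focal node i (id 0, inactive) has two active incoming neighbours j
#' (id 1) and l (id 2); j itself has three active incoming neighbours and l
#' has two, all distinct. The induced index of the focal node is therefore
#' max(3, 2) = 3: with threshold m <= 3 the focal node activates, with
#' m >= 4 it does not.
#'
#' @return List with `graph` (a `netgraph`), `states` (0/1 vector), and
#'   `focal` (the focal node id, 0).
#' @examples
#' fx <- make_induced_index_fixture()
#' induced_index(fx$graph, fx$states, fx$focal)
#' @export
make_induced_index_fixture <- function() {
  edges <- rbind(
    c(1L, 0L), c(2L, 0L),             # j -> i, l -> i
    c(3L, 1L), c(4L, 1L), c(5L, 1L),  # three active in-neighbours of j
    c(6L, 2L), c(7L, 2L))             # two active in-neighbours of l
  graph <- new_netgraph(8L, TRUE, edges)
  states <- c(0L, rep.int(1L, 7L))
  list(graph = graph, states = states, focal = 0L)
}

#' Two-wave cascade fixture
#'
#' A 7-node directed graph (threshold m = 2) in which one induced activation
#' enables a second: node 3 is activated by the inducing hub 2 (two active
#' in-neighbours), and node 3's activation raises node 5's active in-count
#' to two, which lets 5 induce node 6. The expected fixed point (all nodes
#' active) was computed with a full-sweep reference cascade.
#'
#' @return List with `graph`, `init` (0/1 vector), `m`, and `expected`
#'   (the fixed-point 0/1 vector).
#' @export
make_cascade_fixture <- function() {
  edges <- rbind(
    c(0L, 2L), c(1L, 2L),  # seeds supporting hub 2
    c(2L, 3L),             # hub induces 3 (wave 1)
    c(4L, 5L), c(3L, 5L),  # 3's activation completes 5's support
    c(5L, 6L))             # 5 induces 6 (wave 2)
  graph <- new_netgraph(7L, TRUE, edges)
  init <- c(1L, 1L, 1L, 0L, 1L, 1L, 0L)
  list(graph = graph, init = init, m = 2L, expected = rep.int(1L, 7L))
}
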