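#' Initial activation states
#'
#' Marks each node independently active (state 1) with probability `q`.
#'
#' @param graph A `netgraph`.
#' @param q Initial activation probability in [0, 1].
#' @param seed Integer seed.
#' @return Integer vector of 0/1 states, length `graph$n`.
#' @export
seed_states <- function(graph, q, seed = NULL) {
  if (!is.numeric(q) || length(q) != 1L || is.na(q) || q < 0 || q > 1)
    stop("`q` must lie in [0, 1]")
  with_seed(seed, as.integer(stats::runif(graph$n) < q))
}

validate_states <- function(graph, states) {
  states <- as.integer(states)
  if (length(states) != graph$n) stop("states length must equal node count")
  if (anyNA(states) || any(states < 0L | states > 1L))
    stop("states must be 0/1")
  states
}

#' Induced index of a node
#'
#' The induced index of node i is the maximum, over i's *active* incoming
#' neighbours j, of j's own count of active incoming neighbours. An inactive
#' node activates in the growth process when its induced index is at least
#' the threshold m. When i has no active incoming neighbour the index is
#' undefined (returned as `NA`): activation is then impossible for any m,
#' because the rule requires at least one active incoming neighbour. For
#' undirected graphs "incoming neighbours" means neighbours.
#'
#' @param graph A `netgraph`.
#' @param states 0/1 state vector.
#' @param node 0-based node id.
#' @return Integer induced index, or `NA` when undefined.
#' @examples
#' fx <- make_induced_index_fixture()
#' induced_index(fx$graph, fx$states, fx$focal) # 3
#' @export
induced_index <- function(graph, states, node) {
  states <- validate_states(graph, states)
  node <- as.integer(node)
  if (length(node) != 1L || is.na(node) || node < 0L || node >= graph$n)
    stop("`node` must be a valid 0-based node id")
  inn <- graph$in_adj[[node + 1L]]
  act <- inn[states[inn + 1L] == 1L]
  if (length(act) == 0L) return(NA_integer_)
  max(vapply(act, function(j) sum(states[graph$in_adj[[j + 1L]] + 1L]),
             integer(1)))
}

#' Run the growth (activation) cascade to its fixed point
#'
#' Repeatedly activates any inactive node whose induced index is defined and
#' at least `m`, until no node changes state. The dynamics are monotone, so
#' the result is the unique least fixed point above the initial state and is
#' independent of update order; the implementation propagates activations
#' with a work queue, re-examining only nodes whose second neighbourhood
#' changed.
#'
#' @param graph A `netgraph`.
#' @param init 0/1 initial state vector.
#' @param m Non-negative integer induction threshold.
#' @return A `cascade_result`: `final_states`, `active_fraction`, `sweeps`
#'   (number of activation waves), `activated_order` (0-based ids of nodes
#'   activated after initialization, in activation order).
#' @export
run_growth <- function(graph, init, m) {
  state <- validate_states(graph, init)
  m <- check_threshold(m)
  n <- graph$n
  out_adj <- graph$out_adj
  act <- which(state == 1L)
  a <- if (length(act))
    tabulate(unlist(out_adj[act], use.names = FALSE) + 1L, nbins = n)
  else integer(n)

  queue <- integer(n); qtail <- 0L
  push <- function(v) { qtail <<- qtail + 1L; queue[qtail] <<- v }
  for (v in act) if (a[v] >= m) push(v)

  activated <- integer(n); ntact <- 0L
  gen <- integer(n) # activation wave per queued inducer
  head <- 1L
  sweeps <- 0L
  while (head <= qtail) {
    j <- queue[head]
    gj <- gen[head]
    head <- head + 1L
    for (i0 in out_adj[[j]]) {
      i <- i0 + 1L
      if (state[i] == 0L) {
        state[i] <- 1L
        ntact <- ntact + 1L
        activated[ntact] <- i0
        sweeps <- max(sweeps, gj + 1L)
        for (w0 in out_adj[[i]]) {
          w <- w0 + 1L
          a[w] <- a[w] + 1L
          if (state[w] == 1L && a[w] == m) { push(w); gen[qtail] <- gj + 1L }
        }
        if (a[i] >= m) { push(i); gen[qtail] <- gj + 1L }
      }
    }
  }
  new_cascade_result(state, sweeps, activated[seq_len(ntact)])
}

check_threshold <- function(m) {
  m <- as.integer(m)
  if (length(m) != 1L || is.na(m) || m < 0L)
    stop("`m` must be a non-negative integer")
  m
}

new_cascade_result <- function(state, sweeps, order) {
  structure(
    list(final_states = state,
         active_fraction = sum(state) / length(state),
         sweeps = as.integer(sweeps),
         activated_order = order),
    class = "cascade_result")
}

#' @export
print.cascade_result <- function(x, ...) {
  cat(sprintf("<cascade_result> active fraction %.6g (%d/%d), %d sweeps\n",
              x$active_fraction, sum(x$final_states), length(x$final_states),
              x$sweeps))
  invisible(x)
}

#' Run the retention (deactivation) cascade to its fixed point
#'
#' All nodes start active. Any active node that is not pinned and whose
#' induced index (in the current state) is undefined or below `m` is
#' deactivated, repeatedly, until stable -- the greatest fixed point of the
#' same induced-support predicate with the pinned nodes held at state 1.
#' With the seeds pinned this is the heterogeneous retention process in which
#' a q-fraction of nodes has threshold 0 and the rest threshold m.
#'
#' @param graph A `netgraph`.
#' @param pinned Integer vector of 0-based node ids held at state 1.
#' @param m Non-negative integer induction threshold.
#' @return A `cascade_result`; `activated_order` lists deactivated nodes in
#'   deactivation order.
#' @export
run_retention <- function(graph, pinned, m) {
  m <- check_threshold(m)
  n <- graph$n
  pinned <- as.integer(pinned)
  if (length(pinned) && (anyNA(pinned) || min(pinned) < 0L || max(pinned) >= n))
    stop("`pinned` must contain valid 0-based node ids")
  out_adj <- graph$out_adj
  state <- rep.int(1L, n)
  is_pinned <- logical(n); is_pinned[pinned + 1L] <- TRUE

  a <- lengths(graph$in_adj)                 # active in-neighbour counts
  inducer <- a >= m                          # all nodes active initially
  s <- if (any(inducer))
    tabulate(unlist(out_adj[which(inducer)], use.names = FALSE) + 1L, nbins = n)
  else integer(n)                            # inducing in-neighbour counts

  queue <- integer(n); qtail <- 0L; queued <- logical(n)
  for (v in seq_len(n))
    if (!is_pinned[v] && s[v] == 0L) {
      qtail <- qtail + 1L; queue[qtail] <- v; queued[v] <- TRUE
    }

  removed <- integer(n); nrem <- 0L
  sweeps <- 0L
  head <- 1L
  while (head <= qtail) {
    i <- queue[head]; head <- head + 1L
    if (state[i] == 0L) next
    state[i] <- 0L
    nrem <- nrem + 1L; removed[nrem] <- i - 1L
    sweeps <- 1L
    drop_inducer <- function(w) {
      for (t0 in out_adj[[w]]) {
        t <- t0 + 1L
        s[t] <<- s[t] - 1L
        if (s[t] == 0L && state[t] == 1L && !is_pinned[t] && !queued[t]) {
          qtail <<- qtail + 1L; queue[qtail] <<- t; queued[t] <<- TRUE
        }
      }
    }
    if (inducer[i]) { inducer[i] <- FALSE; drop_inducer(i) }
    for (w0 in out_adj[[i]]) {
      w <- w0 + 1L
      a[w] <- a[w] - 1L
      if (inducer[w] && a[w] < m) { inducer[w] <- FALSE; drop_inducer(w) }
    }
  }
  # queued flags may go stale after requeueing; a final full check guards the
  # fixed point (cheap relative to the cascade itself)
  repeat {
    unsupported <- which(state == 1L & !is_pinned & s == 0L)
    if (length(unsupported) == 0L) break
    for (i in unsupported) {
      if (state[i] == 0L) next
      state[i] <- 0L
      nrem <- nrem + 1L; removed[nrem] <- i - 1L
      if (inducer[i]) {
        inducer[i] <- FALSE
        for (t0 in out_adj[[i]]) s[t0 + 1L] <- s[t0 + 1L] - 1L
      }
      for (w0 in out_adj[[i]]) {
        w <- w0 + 1L
        a[w] <- a[w] - 1L
        if (inducer[w] && a[w] < m) {
          inducer[w] <- FALSE
          for (t0 in out_adj[[w]]) s[t0 + 1L] <- s[t0 + 1L] - 1L
        }
      }
    }
  }
  new_cascade_result(state, sweeps, removed[seq_len(nrem)])
}

#' Ensemble of growth cascades on freshly sampled networks
#'
#' Samples an independent network and seeding per replicate, runs the growth
#' cascade, and summarizes the active fraction and giant-component fraction
#' (GCC when undirected, GOUT when directed) by their mean and standard error.
#'
#' @param spec A [model_spec()] describing the network family and the
#'   dynamics parameters q and m.
#' @param n Nodes per replicate.
#' @param replicates Number of independent replicates.
#' @param seed Master seed; replicate seeds are derived from it.
#' @return List with per-replicate vectors `active_fraction` and
#'   `giant_fraction`, and fields `mean_active`, `se_active`, `mean_giant`,
#'   `se_giant`, `replicates`.
#' @export
simulate_ensemble <- function(spec, n, replicates, seed = NULL) {
  if (replicates < 1L) stop("`replicates` must be at least 1")
  rep_seeds <- with_seed(seed, sample.int(.Machine$integer.max, replicates))
  pa <- numeric(replicates); pinf <- numeric(replicates)
  for (r in seq_len(replicates)) {
    g <- sample_model_graph(spec, n, rep_seeds[r])
    init <- seed_states(g, spec$q, rep_seeds[r] %% 2000000011 + 1)
    res <- run_growth(g, init, spec$m)
    comp <- components_active(g, res$final_states)
    pa[r] <- res$active_fraction
    pinf[r] <- if (spec$directed) comp$gout_fraction else comp$gcc_fraction
  }
  se <- function(x) if (replicates > 1L) stats::sd(x) / sqrt(replicates) else 0
  list(active_fraction = pa, giant_fraction = pinf,
       mean_active = mean(pa), se_active = se(pa),
       mean_giant = mean(pinf), se_giant = se(pinf),
       replicates = replicates)
}

#' Export / import 0/1 node states as a two-column text file
#'
#' Plain "node state" pairs, one per line, for debugging and interchange.
#'
#' @param states 0/1 state vector.
#' @param sink,source File path or connection.
#' @export
write_states <- function(states, sink) {
  writeLines(sprintf("%d %d", seq_along(states) - 1L, as.integer(states)),
             sink)
  invisible(states)
}

#' @rdname write_states
#' @export
read_states <- function(source) {
  tab <- utils::read.table(source, col.names = c("node", "state"))
  states <- integer(nrow(tab))
  states[tab$node + 1L] <- as.integer(tab$state)
  states
}
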