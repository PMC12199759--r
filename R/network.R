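#' Network container
#'
#' A `netgraph` is a simple graph (no self-loops, no parallel edges) on nodes
#' labelled 0..n-1, directed or undirected. Edges are stored as a two-column
#' integer matrix of 0-based endpoints -- ordered pairs when directed,
#' canonicalized with u < v when undirected -- together with per-node
#' in/out adjacency lists (identical views when undirected).
#'
#' @param n Node count.
#' @param directed Logical.
#' @param edges Two-column integer matrix of 0-based endpoints.
#' @return A `netgraph` with elements `n`, `directed`, `edges`, `in_adj`,
#'   `out_adj`.
#' @keywords internal
new_netgraph <- function(n, directed, edges) {
  n <- as.integer(n)
  stopifnot(n >= 1L)
  edges <- canonical_edges(edges, directed)
  if (nrow(edges) && (max(edges) >= n || min(edges) < 0L))
    stop("edge endpoints must lie in 0..n-1")
  if (any(edges[, 1L] == edges[, 2L])) stop("self-loops are not allowed")
  g <- structure(
    list(n = n, directed = isTRUE(directed), edges = edges,
         in_adj = NULL, out_adj = NULL),
    class = "netgraph")
  if (directed) {
    g$out_adj <- build_adjacency(n, edges[, 1L], edges[, 2L])
    g$in_adj <- build_adjacency(n, edges[, 2L], edges[, 1L])
  } else {
    adj <- build_adjacency(n, c(edges[, 1L], edges[, 2L]),
                           c(edges[, 2L], edges[, 1L]))
    g$out_adj <- adj
    g$in_adj <- adj
  }
  stopifnot(sum(lengths(g$out_adj)) == nrow(edges) * (2L - directed))
  g
}

canonical_edges <- function(edges, directed) {
  edges <- matrix(as.integer(edges), ncol = 2L)
  if (!directed && nrow(edges)) {
    u <- pmin(edges[, 1L], edges[, 2L])
    v <- pmax(edges[, 1L], edges[, 2L])
    edges <- cbind(u, v)
  }
  edges <- unique(edges)
  edges <- edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
  dimnames(edges) <- NULL
  edges
}

build_adjacency <- function(n, from, to) {
  unname(split(as.integer(to), factor(from, levels = 0:(n - 1L))))
}

#' @export
print.netgraph <- function(x, ...) {
  cat(sprintf("<netgraph> %s, %d nodes, %d edges\n",
              if (x$directed) "directed" else "undirected",
              x$n, nrow(x$edges)))
  invisible(x)
}

#' Number of edges of a netgraph
#' @param graph A `netgraph`.
#' @export
edge_count <- function(graph) nrow(graph$edges)

#' Convert a netgraph to an igraph object (1-based vertex ids)
#' @keywords internal
as_igraph <- function(graph) {
  igraph::add_edges(
    igraph::make_empty_graph(n = graph$n, directed = graph$directed),
    as.vector(t(graph$edges)) + 1L)
}

# Run `code` under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
              add = TRUE)
    }
    set.seed(as.integer(seed) %% .Machine$integer.max)
  }
  force(code)
}

#' Sample an Erdos-Renyi random graph
#'
#' Undirected: every unordered pair is an edge independently with probability
#' mean_degree/(n-1). Directed: every ordered pair is an edge independently
#' with the same probability, so the expected in- and out-degrees both equal
#' `mean_degree`.
#'
#' @param n Number of nodes.
#' @param mean_degree Target mean degree, in [0, n-1].
#' @param directed Logical.
#' @param seed Integer seed; identical seeds give identical edge sets.
#' @return A `netgraph`.
#' @examples
#' g <- sample_er(1000, 3, directed = FALSE, seed = 1)
#' @export
sample_er <- function(n, mean_degree, directed = FALSE, seed = NULL) {
  n <- as.integer(n)
  if (n < 1L) stop("`n` must be at least 1")
  if (mean_degree < 0 || (n > 1L && mean_degree > n - 1))
    stop("`mean_degree` must lie in [0, n-1]")
  p <- if (n > 1L) mean_degree / (n - 1) else 0
  with_seed(seed, {
    ig <- igraph::sample_gnp(n, p, directed = directed)
    edges <- igraph::as_edgelist(ig, names = FALSE) - 1L
    new_netgraph(n, directed, edges)
  })
}

#' Sample a configuration-model random graph
#'
#' Degrees are sampled i.i.d. from `dist` and matched by uniformly random stub
#' pairing; self-loops and parallel edges created by the matching are then
#' removed (simple-graph projection; the induced bias vanishes as n grows).
#' For an undirected `degree_dist` the degree-sum parity is repaired by
#' resampling a uniformly chosen node's degree; for a `joint_degree_dist` the
#' in/out stub totals are balanced by resampling uniformly chosen nodes'
#' (kin, kout) pairs, which preserves the target distribution in expectation.
#' The sampled (pre-projection) degree sequence is kept in attribute
#' `sampled_degrees`.
#'
#' @param dist A `degree_dist` (undirected) or `joint_degree_dist` (directed).
#' @param n Number of nodes.
#' @param seed Integer seed.
#' @return A `netgraph`.
#' @export
sample_configuration <- function(dist, n, seed = NULL) {
  n <- as.integer(n)
  if (n < 1L) stop("`n` must be at least 1")
  if (inherits(dist, "joint_degree_dist")) {
    if (!dist$synthesizable)
      stop("joint distribution is not synthesizable: |mean_in - mean_out| >= 1e-9")
    with_seed(seed, sample_configuration_directed(dist, n))
  } else if (inherits(dist, "degree_dist")) {
    with_seed(seed, sample_configuration_undirected(dist, n))
  } else stop("`dist` must be a degree_dist or joint_degree_dist")
}

sample_configuration_undirected <- function(dist, n) {
  draw <- function(size)
    dist$support[sample.int(length(dist$support), size, replace = TRUE,
                            prob = dist$mass)]
  deg <- draw(n)
  while (sum(deg) %% 2L != 0L) {
    i <- sample.int(n, 1L)
    deg[i] <- draw(1L)
  }
  stubs <- rep.int(0:(n - 1L), deg)
  stubs <- stubs[sample.int(length(stubs))]
  half <- length(stubs) %/% 2L
  edges <- cbind(stubs[seq_len(half) * 2L - 1L], stubs[seq_len(half) * 2L])
  edges <- edges[edges[, 1L] != edges[, 2L], , drop = FALSE]
  g <- new_netgraph(n, FALSE, edges)
  attr(g, "sampled_degrees") <- deg
  g
}

sample_configuration_directed <- function(dist, n) {
  idx <- sample.int(length(dist$mass), n, replace = TRUE, prob = dist$mass)
  kin <- dist$kin[idx]; kout <- dist$kout[idx]
  # balance in/out stub totals by resampling uniformly chosen nodes' degree
  # pairs; the running total difference is tracked incrementally and the
  # replacement draws are batched for speed
  imbalance <- sum(kin) - sum(kout)
  while (imbalance != 0L) {
    nodes <- sample.int(n, 1024L, replace = TRUE)
    repl <- sample.int(length(dist$mass), 1024L, replace = TRUE,
                       prob = dist$mass)
    for (b in seq_len(1024L)) {
      i <- nodes[b]; j <- repl[b]
      imbalance <- imbalance - (kin[i] - kout[i]) +
        (dist$kin[j] - dist$kout[j])
      kin[i] <- dist$kin[j]; kout[i] <- dist$kout[j]
      if (imbalance == 0L) break
    }
  }
  from <- rep.int(0:(n - 1L), kout)
  to <- rep.int(0:(n - 1L), kin)
  from <- from[sample.int(length(from))]
  to <- to[sample.int(length(to))]
  edges <- cbind(from, to)
  edges <- edges[edges[, 1L] != edges[, 2L], , drop = FALSE]
  g <- new_netgraph(n, TRUE, edges)
  attr(g, "sampled_degrees") <- list(kin = kin, kout = kout)
  g
}

#' Read a whitespace-separated edge list
#'
#' Each non-blank line holds two non-negative integer node labels "u v";
#' lines starting with '#' are comments. Labels are compacted to 0..n-1 in
#' first-appearance order, duplicate edges are collapsed, and self-loops are
#' dropped with a warning.
#'
#' @param source File path or connection.
#' @param directed Logical; how to interpret the pairs.
#' @return A `netgraph`.
#' @export
read_edge_list <- function(source, directed = FALSE) {
  lines <- readLines(source)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  toks <- strsplit(trimws(lines[keep]), "\\s+")
  bad <- which(lengths(toks) != 2L |
                 !vapply(toks, function(t) all(grepl("^[0-9]+$", t)), logical(1)))
  if (length(bad))
    stop(sprintf("malformed edge-list line %d: '%s'",
                 keep[bad[1L]], lines[keep[bad[1L]]]))
  if (length(toks) == 0L) stop("edge list contains no edges")
  u <- vapply(toks, function(t) t[1L], character(1))
  v <- vapply(toks, function(t) t[2L], character(1))
  labels <- unique(as.vector(rbind(u, v)))
  ui <- match(u, labels) - 1L
  vi <- match(v, labels) - 1L
  loops <- ui == vi
  if (any(loops)) {
    warning(sprintf("dropped %d self-loop(s)", sum(loops)))
    ui <- ui[!loops]; vi <- vi[!loops]
  }
  new_netgraph(length(labels), directed, cbind(ui, vi))
}

#' Write a netgraph as a plain-text edge list
#'
#' Inverse of [read_edge_list()] on canonical graphs (0-based labels, one
#' "u v" pair per line). Isolated nodes have no representation in the
#' format, so write-then-read shrinks the node count when the graph has
#' degree-zero nodes.
#'
#' @param graph A `netgraph`.
#' @param sink File path or connection.
#' @export
write_edge_list <- function(graph, sink) {
  writeLines(sprintf("%d %d", graph$edges[, 1L], graph$edges[, 2L]), sink)
  invisible(graph)
}
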