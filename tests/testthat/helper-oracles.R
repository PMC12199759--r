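# Brute-force reference implementations used as independent oracles.

# Random simple digraph / graph via independent edge draws.
rand_graph <- function(n, p, directed, seed) {
  set.seed(seed)
  pairs <- expand.grid(u = 0:(n - 1L), v = 0:(n - 1L))
  pairs <- pairs[pairs$u != pairs$v, ]
  if (!directed) pairs <- pairs[pairs$u < pairs$v, ]
  keep <- stats::runif(nrow(pairs)) < p
  growthperc:::new_netgraph(n, directed,
                            cbind(pairs$u[keep], pairs$v[keep]))
}

# Induced index by exhaustive enumeration of in-neighbours of in-neighbours.
oracle_induced_index <- function(graph, states, node) {
  inn <- graph$in_adj[[node + 1L]]
  act <- inn[states[inn + 1L] == 1L]
  if (length(act) == 0L) return(NA_integer_)
  counts <- vapply(act, function(j) {
    jin <- graph$in_adj[[j + 1L]]
    sum(states[jin + 1L])
  }, integer(1))
  max(counts)
}

# Growth fixed point by repeated full sweeps until stable, visiting nodes in
# the given order each sweep.
oracle_growth <- function(graph, init, m, order = seq_len(graph$n)) {
  state <- as.integer(init)
  repeat {
    changed <- FALSE
    for (v in order) {
      if (state[v] == 0L) {
        mi <- oracle_induced_index(graph, state, v - 1L)
        if (!is.na(mi) && mi >= m) {
          state[v] <- 1L
          changed <- TRUE
        }
      }
    }
    if (!changed) return(state)
  }
}

# Retention fixed point by repeated full sweeps.
oracle_retention <- function(graph, pinned, m) {
  state <- rep.int(1L, graph$n)
  is_pinned <- logical(graph$n)
  is_pinned[pinned + 1L] <- TRUE
  repeat {
    changed <- FALSE
    for (v in seq_len(graph$n)) {
      if (state[v] == 1L && !is_pinned[v]) {
        mi <- oracle_induced_index(graph, state, v - 1L)
        if (is.na(mi) || mi < m) {
          state[v] <- 0L
          changed <- TRUE
        }
      }
    }
    if (!changed) return(state)
  }
}

# GSCC / GOUT by boolean transitive closure (n <= ~60).
oracle_components_directed <- function(graph, states) {
  n <- graph$n
  active <- which(states == 1L)
  if (length(active) == 0L)
    return(list(gscc = 0L, gout = 0L))
  reach <- diag(TRUE, n)
  for (e in seq_len(nrow(graph$edges)))
    reach[graph$edges[e, 1L] + 1L, graph$edges[e, 2L] + 1L] <- TRUE
  reach[-active, ] <- FALSE
  reach[, -active] <- FALSE
  diag(reach)[active] <- TRUE
  for (k in active)
    reach <- reach | outer(reach[, k], reach[k, ], "&")
  scc_id <- integer(n)
  next_id <- 0L
  for (v in active) {
    if (scc_id[v] == 0L) {
      next_id <- next_id + 1L
      members <- active[reach[v, active] & reach[active, v]]
      scc_id[members] <- next_id
    }
  }
  sizes <- tabulate(scc_id[active])
  gout <- 0L
  for (id in which(sizes == max(sizes))) {
    members <- which(scc_id == id)
    out_set <- active[colSums(reach[members, active, drop = FALSE]) > 0]
    gout <- max(gout, length(union(members, out_set)))
  }
  list(gscc = max(sizes), gout = gout)
}

oracle_gcc <- function(graph, states) {
  n <- graph$n
  active <- which(states == 1L)
  if (length(active) == 0L) return(0L)
  parent <- seq_len(n)
  find <- function(a) { while (parent[a] != a) a <- parent[a]; a }
  for (e in seq_len(nrow(graph$edges))) {
    u <- graph$edges[e, 1L] + 1L; v <- graph$edges[e, 2L] + 1L
    if (states[u] == 1L && states[v] == 1L) {
      ru <- find(u); rv <- find(v)
      if (ru != rv) parent[ru] <- rv
    }
  }
  roots <- vapply(active, find, integer(1))
  max(tabulate(match(roots, unique(roots))))
}

# Explicit t-sum for the induced-connection kernel H(y, xi, yi; k):
# sum over the number t >= 1 of inducing links, with the per-link
# conditional connection probabilities yi/y and (xi - yi)/(1 - y).
oracle_h_tsum <- function(y, xi, yi, k) {
  if (k == 0L) return(0)
  total <- 0
  for (t in 1:k) {
    pin <- if (y < 1e-14) 0 else yi / y
    pout <- if (1 - y < 1e-14) 0 else (xi - yi) / (1 - y)
    total <- total + choose(k, t) * y^t * (1 - y)^(k - t) *
      (1 - (1 - pin)^t * (1 - pout)^(k - t))
  }
  total
}

# Explicit t-sums for the undirected stage-2 per-degree terms: the
# connection probability of a node with s active supports (t of which can
# induce it), without (eq13) and with (eq14) the downstream factor for the
# k-1-s inducible neighbours.
oracle_eq13_tsum <- function(s, x, y, be, ga) {
  if (s == 0L) return(0)
  rt <- if (x < 1e-14) 0 else y / x
  p1 <- if (y < 1e-14) 0 else ga / y
  p2 <- if (x - y < 1e-14) 0 else (be - ga) / (x - y)
  total <- 0
  for (t in 1:s)
    total <- total + choose(s, t) * rt^t * (1 - rt)^(s - t) *
      (1 - (1 - p1)^t * (1 - p2)^(s - t))
  total
}

oracle_eq14_tsum <- function(s, ks, x, y, al, be, ga) {
  if (s == 0L) return(0)
  rt <- if (x < 1e-14) 0 else y / x
  p1 <- if (y < 1e-14) 0 else ga / y
  p2 <- if (x - y < 1e-14) 0 else (be - ga) / (x - y)
  D <- if (1 - x < 1e-14) 1 else 1 - (al - be) / (1 - x)
  total <- 0
  for (t in 1:s)
    total <- total + choose(s, t) * rt^t * (1 - rt)^(s - t) *
      (1 - (1 - p1)^t * (1 - p2)^(s - t) * D^ks)
  total
}

# Corresponding closed forms as derived by summing the binomial series.
closed_eq13 <- function(s, x, y, be, ga) {
  rt <- if (x < 1e-14) 0 else y / x
  rb <- if (x < 1e-14) 0 else be / x
  Rr <- if (x < 1e-14) 0 else (x - y - be + ga) / x
  1 - (1 - rt)^s - (1 - rb)^s + Rr^s
}

closed_eq14 <- function(s, ks, x, y, al, be, ga) {
  rt <- if (x < 1e-14) 0 else y / x
  rb <- if (x < 1e-14) 0 else be / x
  Rr <- if (x < 1e-14) 0 else (x - y - be + ga) / x
  D <- if (1 - x < 1e-14) 1 else 1 - (al - be) / (1 - x)
  1 - (1 - rt)^s - ((1 - rb)^s - Rr^s) * D^ks
}

# Random feasible argument set for the stage-2 oracles: probabilities with
# the orderings y <= x, ga <= be <= x, ga <= y, be - ga <= x - y, al >= be.
rand_stage2_args <- function() {
  x <- stats::runif(1, 0.05, 1)
  y <- stats::runif(1, 0, x)
  be <- stats::runif(1, 0, x)
  ga <- stats::runif(1, max(0, be - (x - y)), min(be, y))
  al <- stats::runif(1, be, min(1, be + (1 - x)))
  list(x = x, y = y, al = al, be = be, ga = ga)
}
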