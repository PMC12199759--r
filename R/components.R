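#' Giant components of the active subgraph
#'
#' Restricts the graph to its state-1 nodes. For undirected graphs the report
#' gives the largest connected component (GCC) of the active subgraph. For
#' directed graphs it gives the largest strongly connected component (GSCC)
#' and the giant out-component GOUT, defined bow-tie style as the GSCC plus
#' all active nodes reachable from it along directed paths inside the active
#' subgraph (so GOUT always contains the GSCC).
#'
#' @param graph A `netgraph`.
#' @param states 0/1 state vector.
#' @return A `component_report`: for undirected graphs `gcc_nodes` and
#'   `gcc_fraction`; for directed graphs `gscc_nodes`, `gscc_fraction`,
#'   `gout_nodes` and `gout_fraction`. Fractions are counts divided by the
#'   full node count n.
#' @export
components_active <- function(graph, states) {
  states <- validate_states(graph, states)
  n <- graph$n
  active <- which(states == 1L)  # 1-based vertex ids
  if (length(active) == 0L) {
    rep0 <- if (graph$directed)
      list(gscc_nodes = 0L, gscc_fraction = 0, gout_nodes = 0L,
           gout_fraction = 0)
    else list(gcc_nodes = 0L, gcc_fraction = 0)
    return(structure(rep0, class = "component_report"))
  }
  sub <- igraph::induced_subgraph(as_igraph(graph), active)
  if (!graph$directed) {
    comp <- igraph::components(sub)
    gcc <- max(comp$csize)
    return(structure(list(gcc_nodes = as.integer(gcc), gcc_fraction = gcc / n),
                     class = "component_report"))
  }
  comp <- igraph::components(sub, mode = "strong")
  gscc <- max(comp$csize)
  # ties among maximal strongly connected components are resolved in favour
  # of the one with the largest out-component
  gout <- 0L
  for (cid in which(comp$csize == gscc)) {
    v <- which(comp$membership == cid)[1L]
    gout <- max(gout, length(igraph::subcomponent(sub, v, mode = "out")))
  }
  gout <- max(gout, gscc)
  structure(
    list(gscc_nodes = as.integer(gscc), gscc_fraction = gscc / n,
         gout_nodes = as.integer(gout), gout_fraction = gout / n),
    class = "component_report")
}

#' @export
print.component_report <- function(x, ...) {
  if (!is.null(x$gcc_nodes))
    cat(sprintf("<component_report> GCC %d nodes (fraction %.6g)\n",
                x$gcc_nodes, x$gcc_fraction))
  else
    cat(sprintf(
      "<component_report> GSCC %d nodes, GOUT %d nodes (fraction %.6g)\n",
      x$gscc_nodes, x$gout_nodes, x$gout_fraction))
  invisible(x)
}

#' Model specification for scans, ensembles and the CLI
#'
#' Bundles a network family with the dynamics parameters. For family `"er"`
#' the connectivity parameter is `mean_degree` (Poisson degrees); for family
#' `"sf"` it is the power-law exponent `gamma` on support `kmin..kmax`.
#'
#' @param family `"er"` or `"sf"`.
#' @param directed Logical.
#' @param q Initial active fraction in [0, 1].
#' @param m Non-negative integer induction threshold.
#' @param mean_degree Mean degree (ER family).
#' @param gamma Power-law exponent (SF family).
#' @param kmin,kmax Power-law support bounds (SF family).
#' @return A `model_spec` list.
#' @export
model_spec <- function(family = c("er", "sf"), directed = FALSE, q, m,
                       mean_degree = NULL, gamma = NULL,
                       kmin = 1L, kmax = 100L) {
  family <- match.arg(family)
  if (q < 0 || q > 1) stop("`q` must lie in [0, 1]")
  m <- check_threshold(m)
  if (family == "er" && is.null(mean_degree))
    stop("ER spec requires `mean_degree`")
  if (family == "sf" && is.null(gamma))
    stop("SF spec requires `gamma`")
  structure(
    list(family = family, directed = isTRUE(directed), q = q, m = m,
         mean_degree = mean_degree, gamma = gamma,
         kmin = as.integer(kmin), kmax = as.integer(kmax)),
    class = "model_spec")
}

#' Degree distribution implied by a model spec
#' @keywords internal
spec_dist <- function(spec) {
  if (spec$family == "er") {
    if (spec$directed) er_joint(spec$mean_degree)
    else poisson_degree_distribution(spec$mean_degree)
  } else {
    if (spec$directed) joint_powerlaw_distribution(spec$gamma, spec$kmin, spec$kmax)
    else powerlaw_degree_distribution(spec$gamma, spec$kmin, spec$kmax)
  }
}

#' Sample a concrete graph from a model spec
#' @keywords internal
sample_model_graph <- function(spec, n, seed = NULL) {
  if (spec$family == "er")
    sample_er(n, spec$mean_degree, directed = spec$directed, seed = seed)
  else
    sample_configuration(spec_dist(spec), n, seed = seed)
}
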