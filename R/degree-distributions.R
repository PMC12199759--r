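#' Degree distributions
#'
#' A `degree_dist` holds a finite discrete degree distribution P(k): a sorted
#' integer support, a probability mass per support value (summing to one), and
#' the cached mean degree. A `joint_degree_dist` holds a joint in/out-degree
#' distribution P(kin, kout) for directed networks, stored as distinct
#' (kin, kout) pairs with their masses and the two marginal means. A directed
#' degree sequence is realizable only when the mean in- and out-degrees agree,
#' so joint distributions carry a `synthesizable` flag.
#'
#' @param support Sorted distinct non-negative integer degrees.
#' @param mass Probability mass per support value; must be non-negative and
#'   is validated to sum to one within 1e-12.
#' @return An object of class `degree_dist` with elements `support`, `mass`
#'   and `mean_degree`.
#' @keywords internal
new_degree_dist <- function(support, mass) {
  support <- as.integer(support)
  if (anyDuplicated(support) || is.unsorted(support, strictly = TRUE))
    stop("support must be sorted distinct integers")
  if (any(support < 0L)) stop("degrees must be non-negative")
  if (length(mass) != length(support)) stop("support/mass length mismatch")
  if (any(mass < 0)) stop("masses must be non-negative")
  if (abs(sum(mass) - 1) > 1e-12) stop("masses must sum to 1 within 1e-12")
  structure(
    list(support = support, mass = as.numeric(mass),
         mean_degree = sum(support * mass)),
    class = "degree_dist")
}

#' @keywords internal
new_joint_degree_dist <- function(kin, kout, mass) {
  kin <- as.integer(kin); kout <- as.integer(kout)
  if (any(kin < 0L) || any(kout < 0L)) stop("degrees must be non-negative")
  if (anyDuplicated(cbind(kin, kout))) stop("duplicate (kin, kout) pairs")
  if (any(mass < 0)) stop("masses must be non-negative")
  if (abs(sum(mass) - 1) > 1e-12) stop("masses must sum to 1 within 1e-12")
  mean_in <- sum(kin * mass); mean_out <- sum(kout * mass)
  structure(
    list(kin = kin, kout = kout, mass = as.numeric(mass),
         mean_in = mean_in, mean_out = mean_out,
         synthesizable = abs(mean_in - mean_out) < 1e-9),
    class = "joint_degree_dist")
}

#' Truncated Poisson degree distribution
#'
#' The Poisson distribution is the degree distribution of large Erdos-Renyi
#' random graphs with mean degree `mean`. The infinite support is truncated at
#' the smallest kmax whose upper tail mass falls below `tail_tolerance` and the
#' remaining masses are renormalized to sum to one.
#'
#' @param mean Positive mean degree.
#' @param tail_tolerance Truncation tolerance for the Poisson tail mass;
#'   must lie in (0, 1e-6).
#' @return A `degree_dist` on support 0..kmax.
#' @examples
#' d <- poisson_degree_distribution(3)
#' abs(d$mean_degree - 3) < 1e-9
#' @export
poisson_degree_distribution <- function(mean, tail_tolerance = 1e-12) {
  if (!is.numeric(mean) || length(mean) != 1L || !is.finite(mean) || mean <= 0)
    stop("`mean` must be a positive number")
  if (tail_tolerance <= 0 || tail_tolerance >= 1e-6)
    stop("`tail_tolerance` must lie in (0, 1e-6)")
  kmax <- stats::qpois(tail_tolerance, mean, lower.tail = FALSE)
  while (stats::ppois(kmax, mean, lower.tail = FALSE) >= tail_tolerance)
    kmax <- kmax + 1L
  k <- 0:kmax
  mass <- stats::dpois(k, mean)
  new_degree_dist(k, mass / sum(mass))
}

#' Power-law degree distribution
#'
#' P(k) proportional to k^(-gamma) on the bounded support kmin..kmax, exactly
#' normalized. This is the scale-free family used throughout the phase
#' analysis (default bounds 1..100).
#'
#' @param gamma Positive power-law exponent.
#' @param kmin,kmax Positive integer support bounds, kmin <= kmax.
#' @return A `degree_dist` on support kmin..kmax.
#' @examples
#' d <- powerlaw_degree_distribution(3, 1, 100)
#' @export
powerlaw_degree_distribution <- function(gamma, kmin = 1L, kmax = 100L) {
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma <= 0)
    stop("`gamma` must be positive")
  kmin <- as.integer(kmin); kmax <- as.integer(kmax)
  if (kmin < 1L) stop("`kmin` must be a positive integer")
  if (kmin > kmax) stop("`kmin` must not exceed `kmax`")
  k <- kmin:kmax
  w <- k^(-gamma)
  new_degree_dist(k, w / sum(w))
}

#' Uncorrelated joint power-law distribution
#'
#' Product-form joint distribution P(kin, kout) proportional to
#' kin^(-gamma) * kout^(-gamma): in- and out-degrees are independent and share
#' the same bounded power-law marginal, so the mean in- and out-degrees are
#' equal by symmetry.
#'
#' @inheritParams powerlaw_degree_distribution
#' @return A `joint_degree_dist` with product-form masses.
#' @export
joint_powerlaw_distribution <- function(gamma, kmin = 1L, kmax = 100L) {
  marg <- powerlaw_degree_distribution(gamma, kmin, kmax)
  joint_from_marginals(marg, marg)
}

#' Independent-Poisson joint distribution for directed ER networks
#'
#' Product of two truncated Poisson marginals with the same mean: the joint
#' in/out-degree distribution of a large directed Erdos-Renyi graph in which
#' every ordered pair is linked independently.
#'
#' @inheritParams poisson_degree_distribution
#' @return A `joint_degree_dist`.
#' @export
er_joint <- function(mean, tail_tolerance = 1e-12) {
  marg <- poisson_degree_distribution(mean, tail_tolerance)
  joint_from_marginals(marg, marg)
}

#' Product-form joint distribution from two marginals
#' @keywords internal
joint_from_marginals <- function(din, dout) {
  grid <- expand.grid(i = seq_along(din$support), o = seq_along(dout$support))
  new_joint_degree_dist(
    kin = din$support[grid$i],
    kout = dout$support[grid$o],
    mass = din$mass[grid$i] * dout$mass[grid$o])
}

#' In-degree marginal of a joint distribution
#' @keywords internal
joint_in_marginal <- function(joint) {
  m <- rowsum(joint$mass, joint$kin)
  kin <- as.integer(rownames(m))
  ord <- order(kin)
  new_degree_dist(kin[ord], m[ord] / sum(m))
}

#' Out-degree marginal of a joint distribution
#' @keywords internal
joint_out_marginal <- function(joint) {
  m <- rowsum(joint$mass, joint$kout)
  kout <- as.integer(rownames(m))
  ord <- order(kout)
  new_degree_dist(kout[ord], m[ord] / sum(m))
}

#' @export
print.degree_dist <- function(x, ...) {
  cat(sprintf("<degree_dist> support %d..%d, mean degree %.6g\n",
              min(x$support), max(x$support), x$mean_degree))
  invisible(x)
}

#' @export
print.joint_degree_dist <- function(x, ...) {
  cat(sprintf(
    "<joint_degree_dist> %d (kin,kout) pairs, mean in %.6g, mean out %.6g%s\n",
    length(x$mass), x$mean_in, x$mean_out,
    if (x$synthesizable) " (synthesizable)" else ""))
  invisible(x)
}
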