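#' Stable binomial probability term
#'
#' C(n, s) p^s (1-p)^(n-s), the probability that exactly s of n independent
#' trials with success probability p succeed. Evaluated in log space (via
#' [stats::dbinom()]), so it is stable for large n.
#'
#' @param p Success probability in [0, 1].
#' @param n Number of trials.
#' @param s Number of successes, 0 <= s <= n.
#' @return The binomial probability.
#' @export
binomial_term <- function(p, n, s) {
  if (any(p < 0 | p > 1)) stop("`p` must lie in [0, 1]")
  if (any(s < 0 | s > n)) stop("`s` must lie in 0..n")
  stats::dbinom(s, n, p)
}

#' Closed form of the induced-connection kernel
#'
#' H(y, xi, yi; k) = 1 - (1-y)^k - (1-xi)^k + (1-y-xi+yi)^k: the probability
#' that a node with k incoming links connects to the giant out-component
#' through at least one of them, given it started inactive, when each link
#' independently induces it with probability y, connects it onward with
#' probability xi, and does both with probability yi. Equal to the explicit
#' binomial double sum over the number of inducing links.
#'
#' @param y,xi,yi Link-level probabilities with yi <= y, xi - yi <= 1 - y.
#' @param k Non-negative integer link count (0 gives 0).
#' @return The kernel value in [0, 1].
#' @export
h_closed <- function(y, xi, yi, k) {
  1 - (1 - y)^k - (1 - xi)^k + (1 - y - xi + yi)^k
}

# 0/0 -> 0 convention: conditioning events with probability below 1e-14 never
# occur, so conditional probabilities on them are taken as 0.
safe_div <- function(num, den) {
  if (den < 1e-14) 0 else min(max(num / den, 0), 1)
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

# -- undirected solver -------------------------------------------------------

# One simultaneous update of the stage-1 pair (x~, y~) for an undirected
# degree distribution. k, w: degrees with their edge-end weights kP(k)/<k>.
# Inner binomial sums are collapsed to closed form: the full sum
# sum_s C(n,s) x^s (1-x)^(n-s) u^s equals (1 - x + x u)^n, and only the
# s < m leading terms are corrected explicitly.
step1_undirected <- function(x, y, k, w, q, m) {
  n1 <- k - 1
  xn <- q + (1 - q) * sum(w * (1 - (1 - y)^n1))
  r <- safe_div(y, x)
  corrA <- 0; corrB <- 0
  if (m > 0) for (s in 0:(m - 1)) {
    Fs <- stats::dbinom(s, n1, x)
    corrA <- corrA + Fs
    corrB <- corrB + Fs * (1 - r)^s
  }
  A <- pmax(1 - corrA, 0)
  B <- pmax((1 - y)^n1 - corrB, 0)
  yn <- sum(w * (q * A + (1 - q) * pmax(A - B, 0)))
  c(min(max(xn, 0), 1), min(max(yn, 0), 1))
}

pa_undirected <- function(x, y, k, pk, q) {
  q + (1 - q) * sum(pk * (1 - (1 - y)^k))
}

# One simultaneous update of the stage-2 triple (alpha, beta, gamma) with the
# stage-1 pair (x, y) frozen.
step2_undirected <- function(al, be, ga, x, y, k, w, q, m) {
  n1 <- k - 1
  r <- safe_div(y, x)
  rb <- safe_div(be, x)
  Rr <- safe_div(x - y - be + ga, x)
  D <- 1 - safe_div(al - be, 1 - x)
  ub <- 1 - rb
  full_bD <- (x * ub + (1 - x) * D)^n1
  full_RD <- (x * Rr + (1 - x) * D)^n1
  full_r <- (1 - y)^n1
  # corrections over s = 0..m-2 (split at m-1) and s = 0..m-1 (split at m)
  C1 <- C2 <- C3 <- C4 <- 0          # s <= m-2
  C1b <- C2b <- C3b <- C4b <- CFb <- CRb <- 0  # s <= m-1
  if (m > 0) for (s in 0:(m - 1)) {
    Fs <- stats::dbinom(s, n1, x)
    Ds <- D^pmax(n1 - s, 0)
    if (s <= m - 2) {
      C1 <- C1 + Fs * ub^s
      C2 <- C2 + Fs * ub^s * Ds
      C3 <- C3 + Fs * Rr^s
      C4 <- C4 + Fs * Rr^s * Ds
    }
    C1b <- C1b + Fs * ub^s
    C2b <- C2b + Fs * ub^s * Ds
    C3b <- C3b + Fs * Rr^s
    C4b <- C4b + Fs * Rr^s * Ds
    CFb <- CFb + Fs
    CRb <- CRb + Fs * (1 - r)^s
  }
  aln <- sum(w * (1 - C1 - full_bD + C2))
  inner_b <- 1 - full_r - C1 - full_bD + C2 + C3 + full_RD - C4
  ben <- q * aln + (1 - q) * sum(w * inner_b)
  g_q <- (1 - CFb) - (full_bD - C2b)
  g_nq <- (1 - CFb) - (full_r - CRb) - (full_bD - C2b) + (full_RD - C4b)
  gan <- sum(w * (q * g_q + (1 - q) * g_nq))
  c(min(max(aln, 0), 1), min(max(ben, 0), 1), min(max(gan, 0), 1))
}

pinf_undirected <- function(al, be, ga, x, y, k, pk, q, m) {
  r <- safe_div(y, x)
  rb <- safe_div(be, x)
  Rr <- safe_div(x - y - be + ga, x)
  D <- 1 - safe_div(al - be, 1 - x)
  ub <- 1 - rb
  fullk_bD <- (x * ub + (1 - x) * D)^k
  fullk_RD <- (x * Rr + (1 - x) * D)^k
  fullk_r <- (1 - y)^k
  K1 <- K2 <- K3 <- K4 <- 0          # s <= m-1, n = k trials
  if (m > 0) for (s in 0:(m - 1)) {
    Fs <- stats::dbinom(s, k, x)
    Ds <- D^pmax(k - s, 0)
    K1 <- K1 + Fs * ub^s
    K2 <- K2 + Fs * ub^s * Ds
    K3 <- K3 + Fs * Rr^s
    K4 <- K4 + Fs * Rr^s * Ds
  }
  part_q <- 1 - K1 - fullk_bD + K2
  part_nq <- 1 - fullk_r - K1 - fullk_bD + K2 + K3 + fullk_RD - K4
  min(max(sum(pk * (q * part_q + (1 - q) * part_nq)), 0), 1)
}

#' Solve the undirected mean-field equations
#'
#' Two-stage fixed-point solution for an undirected network with degree
#' distribution `dist`, initial active fraction `q` and induction threshold
#' `m`. Stage 1 iterates the link-level pair (x~, y~) -- the probabilities
#' that the node at the far end of a random link is active without help from
#' the near end, and that it can induce the near end -- to a fixed point, and
#' evaluates the final active fraction Pa. Stage 2 freezes (x~, y~) and
#' iterates the giant-component triple (alpha, beta, gamma) to obtain the GCC
#' size P_inf.
#'
#' The `lower` branch initializes stage 1 at the activation floor (q, 0) and
#' converges to the least fixed point, which is the steady state of the
#' growth process; the `upper` branch initializes at (1, 1) and converges to
#' the greatest fixed point, the steady state of the retention process with a
#' q-fraction pinned. Stage 2 is initialized at the feasibility-clipped upper
#' corner (1, x~, y~) and iterated down to the giant-component root; the
#' all-zero root always exists and is reported as P_inf = 0 when the
#' iteration collapses below 1e-12.
#'
#' @param dist A `degree_dist`.
#' @param q Initial active fraction in [0, 1].
#' @param m Non-negative integer induction threshold.
#' @param branch `"lower"` (growth) or `"upper"` (retention).
#' @param tol Stage-1 convergence tolerance (max component change).
#' @param max_iter Iteration cap per stage; non-convergence is flagged, not
#'   an error.
#' @param stage2_tol Stage-2 convergence tolerance.
#' @param trace If TRUE, attach the per-iteration stage-1 trajectory.
#' @param init Optional length-2 numeric overriding the branch's stage-1
#'   initialization (used for warm-started continuation along a scan).
#' @return An `undirected_solution` with fields `x_t`, `y_t`, `alpha`,
#'   `beta`, `gamma_v`, `Pa_hat`, `P_inf`, `converged`, `iterations`,
#'   `residual` plus the call parameters.
#' @export
solve_undirected <- function(dist, q, m, branch = c("lower", "upper"),
                             tol = 1e-12, max_iter = 1e6,
                             stage2_tol = 1e-10, trace = FALSE, init = NULL) {
  branch <- match.arg(branch)
  check_qm(q, m)
  k_all <- dist$support; p_all <- dist$mass
  keep <- p_all > 0
  k_all <- k_all[keep]; p_all <- p_all[keep]
  kw <- k_all[k_all >= 1L]
  w <- (k_all * p_all)[k_all >= 1L]
  w <- if (sum(w) > 0) w / sum(w) else w

  st <- if (!is.null(init)) clamp01(as.numeric(init))
  else if (branch == "lower") c(q, 0) else c(1, 1)
  n1 <- kw - 1
  if (trace) {
    tr <- matrix(st, 1L, 2L, dimnames = list(NULL, c("x", "y")))
    it <- 0L; res <- Inf
    while (it < max_iter) {
      stn <- step1_undirected(st[1], st[2], kw, w, q, m)
      res <- max(abs(stn - st))
      it <- it + 1L
      st <- stn
      tr <- rbind(tr, st)
      if (res < tol) break
    }
  } else {
    ch <- outer(0:max(m - 1, 0), n1, function(s, n) choose(n, s))
    s1 <- stage1_loop(n1, w, ch, q, m, st[1], st[2], tol, max_iter)
    st <- c(s1$x, s1$y); it <- as.integer(s1$iterations); res <- s1$residual
  }
  conv1 <- res < tol
  x <- st[1]; y <- st[2]
  pa <- pa_undirected(x, y, k_all, p_all, q)

  Fm <- outer(0:max(m - 1, 0), n1,
              function(s, n) stats::dbinom(s, n, x))
  s2r <- stage2_und_loop(n1, w, Fm, x, y, q, m, 1, x, y,
                         stage2_tol, max_iter)
  s2 <- c(s2r$alpha, s2r$beta, s2r$gamma)
  it2 <- as.integer(s2r$iterations); res2 <- s2r$residual
  conv2 <- res2 < stage2_tol
  pinf <- if (s2[1] < 1e-12) 0
  else pinf_undirected(s2[1], s2[2], s2[3], x, y, k_all, p_all, q, m)
  out <- structure(
    list(x_t = x, y_t = y, alpha = s2[1], beta = s2[2], gamma_v = s2[3],
         Pa_hat = pa, P_inf = min(pinf, pa),
         converged = conv1 && conv2, iterations = it + it2,
         residual = max(res, res2),
         q = q, m = m, branch = branch, mean_degree = dist$mean_degree),
    class = "undirected_solution")
  if (trace) attr(out, "trace") <- tr
  out
}

check_qm <- function(q, m) {
  if (!is.numeric(q) || length(q) != 1L || is.na(q) || q < 0 || q > 1)
    stop("`q` must lie in [0, 1]")
  check_threshold(m)
}

# -- directed solver ---------------------------------------------------------

# Collapse a joint in/out-degree distribution to the two weight vectors the
# directed equations need: the edge-end weight w(kin) = sum_kout kout
# P(kin,kout)/<k> (the in-degree distribution of the node an incoming link
# points from ... i.e. of node i on a random link i->j), and the plain
# in-degree marginal P(kin).
collapse_joint <- function(joint) {
  mk <- sum(joint$kout * joint$mass)
  wtab <- rowsum(joint$kout * joint$mass / mk, joint$kin)
  ptab <- rowsum(joint$mass, joint$kin)
  kin <- as.integer(rownames(ptab))
  ord <- order(kin)
  list(kin = kin[ord], w = as.numeric(wtab)[ord], pin = as.numeric(ptab)[ord],
       mean_degree = mk)
}

step1_directed <- function(x, y, kin, w, q, m) {
  xn <- q + (1 - q) * sum(w * (1 - (1 - y)^kin))
  r <- safe_div(y, x)
  corrA <- 0; corrB <- 0
  if (m > 0) for (s in 0:(m - 1)) {
    Fs <- stats::dbinom(s, kin, x)
    corrA <- corrA + Fs
    corrB <- corrB + Fs * (1 - r)^s
  }
  A <- pmax(1 - corrA, 0)
  B <- pmax((1 - y)^kin - corrB, 0)
  yn <- sum(w * (q * A + (1 - q) * pmax(A - B, 0)))
  c(min(max(xn, 0), 1), min(max(yn, 0), 1))
}

step2_directed <- function(xi, yi, x, y, kin, w, q, m) {
  r <- safe_div(y, x)
  rxi <- safe_div(xi, x)
  ryi <- safe_div(yi, x)
  uH <- clamp01(1 - r - rxi + ryi)
  full_xi <- (1 - xi)^kin
  full_y <- (1 - y)^kin
  full_H <- (clamp01(1 - y - xi + yi))^kin
  A <- 0; Cxi <- 0; Cr <- 0; CH <- 0   # corrections over s <= m-1
  if (m > 0) {
    A_acc <- 0
    for (s in 0:(m - 1)) {
      Fs <- stats::dbinom(s, kin, x)
      A_acc <- A_acc + Fs
      Cxi <- Cxi + Fs * (1 - rxi)^s
      Cr <- Cr + Fs * (1 - r)^s
      CH <- CH + Fs * uH^s
    }
    A <- A_acc
  }
  tail1 <- pmax(1 - A, 0)                          # sum_{s>=m} F(s)
  tail_xi <- pmax(full_xi - Cxi, 0)                # sum_{s>=m} F (1-rxi)^s
  tail_r <- pmax(full_y - Cr, 0)
  tail_H <- pmax(full_H - CH, 0)
  xin <- q * sum(w * (1 - full_xi)) + (1 - q) * sum(w * h_closed(y, xi, yi, kin))
  yin <- q * sum(w * (tail1 - tail_xi)) +
    (1 - q) * sum(w * pmax(tail1 - tail_r - tail_xi + tail_H, 0))
  c(min(max(xin, 0), 1), min(max(yin, 0), 1))
}

#' Solve the directed mean-field equations
#'
#' Two-stage fixed-point solution for a directed network with joint in/out
#' degree distribution `dist`. Stage 1 iterates the link-level pair (x, y)
#' -- for a random link i -> j, the probability that i is active and the
#' probability that i can induce j -- and evaluates the final active fraction
#' Pa. Stage 2 freezes (x, y) and iterates the giant-out-component pair
#' (x_inf, y_inf) to obtain the GOUT size P_inf. Branch semantics and
#' initialization are as in [solve_undirected()].
#'
#' @param dist A `joint_degree_dist`.
#' @inheritParams solve_undirected
#' @return A `directed_solution` with fields `x`, `y`, `x_inf`, `y_inf`,
#'   `Pa`, `P_inf`, `converged`, `iterations`, `residual` plus the call
#'   parameters.
#' @export
solve_directed <- function(dist, q, m, branch = c("lower", "upper"),
                           tol = 1e-12, max_iter = 1e6,
                           stage2_tol = 1e-10, trace = FALSE, init = NULL) {
  branch <- match.arg(branch)
  check_qm(q, m)
  if (!inherits(dist, "joint_degree_dist"))
    stop("`dist` must be a joint_degree_dist")
  cc <- collapse_joint(dist)
  kin <- cc$kin; w <- cc$w; pin <- cc$pin

  st <- if (!is.null(init)) clamp01(as.numeric(init))
  else if (branch == "lower") c(q, 0) else c(1, 1)
  if (trace) {
    tr <- matrix(st, 1L, 2L, dimnames = list(NULL, c("x", "y")))
    it <- 0L; res <- Inf
    while (it < max_iter) {
      stn <- step1_directed(st[1], st[2], kin, w, q, m)
      res <- max(abs(stn - st))
      it <- it + 1L
      st <- stn
      tr <- rbind(tr, st)
      if (res < tol) break
    }
  } else {
    ch <- outer(0:max(m - 1, 0), kin, function(s, n) choose(n, s))
    s1 <- stage1_loop(kin, w, ch, q, m, st[1], st[2], tol, max_iter)
    st <- c(s1$x, s1$y); it <- as.integer(s1$iterations); res <- s1$residual
  }
  conv1 <- res < tol
  x <- st[1]; y <- st[2]
  pa <- q + (1 - q) * sum(pin * (1 - (1 - y)^kin))

  Fm <- outer(0:max(m - 1, 0), kin,
              function(s, n) stats::dbinom(s, n, x))
  s2r <- stage2_dir_loop(kin, w, Fm, x, y, q, m, x, y, stage2_tol, max_iter)
  s2 <- c(s2r$x_inf, s2r$y_inf)
  it2 <- as.integer(s2r$iterations); res2 <- s2r$residual
  conv2 <- res2 < stage2_tol
  pinf <- if (s2[1] < 1e-12) 0
  else q * sum(pin * (1 - (1 - s2[1])^kin)) +
    (1 - q) * sum(pin * h_closed(y, s2[1], s2[2], kin))
  pinf <- min(max(pinf, 0), 1)
  out <- structure(
    list(x = x, y = y, x_inf = s2[1], y_inf = s2[2],
         Pa = pa, P_inf = min(pinf, pa),
         converged = conv1 && conv2, iterations = it + it2,
         residual = max(res, res2),
         q = q, m = m, branch = branch, mean_degree = cc$mean_degree),
    class = "directed_solution")
  if (trace) attr(out, "trace") <- tr
  out
}

#' @export
print.undirected_solution <- function(x, ...) {
  cat(sprintf(
    "<undirected_solution> q=%.4g m=%d branch=%s: Pa=%.6g P_inf=%.6g (%s, %d iter)\n",
    x$q, x$m, x$branch, x$Pa_hat, x$P_inf,
    if (x$converged) "converged" else "NOT converged", x$iterations))
  invisible(x)
}

#' @export
print.directed_solution <- function(x, ...) {
  cat(sprintf(
    "<directed_solution> q=%.4g m=%d branch=%s: Pa=%.6g P_inf=%.6g (%s, %d iter)\n",
    x$q, x$m, x$branch, x$Pa, x$P_inf,
    if (x$converged) "converged" else "NOT converged", x$iterations))
  invisible(x)
}

#' Serialize a solver solution to JSON
#'
#' All fixed-point fields, parameters and convergence metadata, as a JSON
#' record.
#'
#' @param solution A `directed_solution` or `undirected_solution`.
#' @param path Optional file path; when NULL the JSON string is returned.
#' @export
solution_to_json <- function(solution, path = NULL) {
  rec <- unclass(solution)
  rec$type <- class(solution)[1L]
  js <- jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) js else { writeLines(js, path); invisible(js) }
}
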