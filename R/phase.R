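#' Phase-transition analysis
#'
#' Tools that scan a control parameter of the mean-field theory, classify the
#' resulting phase transition of the giant-component size P_inf (continuous,
#' hybrid, or first-order), locate the continuous onset kcI and the jump
#' point kcII by bisection, find the critical initial fraction q* separating
#' continuous from hybrid behaviour, measure how the jump height scales with
#' q, and assemble growth-versus-retention hysteresis loops.
#'
#' @name phase
NULL

# Solve the theory for `spec` with one scan parameter overridden.
# Returns c(Pa, P_inf, converged, x, y) so scans can warm-start stage 1.
solve_point <- function(spec, parameter, value, branch, init = NULL, ...) {
  sp <- spec
  sp[[parameter]] <- value
  if (sp$directed) {
    s <- solve_directed(spec_dist(sp), sp$q, sp$m, branch = branch,
                        init = init, ...)
    list(Pa = s$Pa, P_inf = s$P_inf, converged = s$converged,
         state = c(s$x, s$y), solution = s)
  } else {
    s <- solve_undirected(spec_dist(sp), sp$q, sp$m, branch = branch,
                          init = init, ...)
    list(Pa = s$Pa_hat, P_inf = s$P_inf, converged = s$converged,
         state = c(s$x_t, s$y_t), solution = s)
  }
}

check_parameter <- function(spec, parameter) {
  ok <- c("mean_degree", "q", "gamma")
  if (!parameter %in% ok)
    stop("`parameter` must be one of ", paste(ok, collapse = ", "))
  if (parameter == "mean_degree" && spec$family != "er")
    stop("mean_degree scans require the ER family")
  if (parameter == "gamma" && spec$family != "sf")
    stop("gamma scans require the SF family")
  parameter
}

# Direction in which the scan parameter increases connectivity: +1 for
# mean_degree and q, -1 for gamma (heavier tails at smaller gamma).
param_direction <- function(parameter) if (parameter == "gamma") -1 else 1

#' Scan a control parameter of the theory
#'
#' Solves the mean-field equations at every grid point, on the lower
#' (growth), upper (retention-initialized), or both branches. Within a
#' branch, each solve can be warm-started from the previous grid point's
#' stage-1 fixed point (continuation), with a cold-start retry if the
#' continuation does not converge.
#'
#' @param spec A [model_spec()].
#' @param parameter `"mean_degree"`, `"q"`, or `"gamma"`.
#' @param grid Sorted numeric grid of parameter values.
#' @param branch `"lower"`, `"upper"`, or `"both"`.
#' @param warm_start Logical; continuation along the grid.
#' @return A `scan_result` data frame with columns `parameter`, `value`,
#'   `branch`, `Pa`, `P_inf`, `converged`.
#' @export
scan_parameter <- function(spec, parameter, grid,
                           branch = c("lower", "upper", "both"),
                           warm_start = TRUE) {
  branch <- match.arg(branch)
  check_parameter(spec, parameter)
  if (length(grid) == 0L || is.unsorted(grid, strictly = TRUE))
    stop("`grid` must be a nonempty strictly increasing numeric vector")
  branches <- if (branch == "both") c("lower", "upper") else branch
  rows <- list()
  for (br in branches) {
    # the upper branch is continued in the direction of decreasing
    # connectivity, the lower branch in increasing direction
    idx <- seq_along(grid)
    dir_up <- param_direction(parameter) > 0
    if ((br == "upper") == dir_up) idx <- rev(idx)
    st <- NULL
    vals <- vector("list", length(grid))
    for (i in idx) {
      pt <- solve_point(spec, parameter, grid[i], br,
                        init = if (warm_start) st else NULL)
      if (!pt$converged && warm_start)
        pt <- solve_point(spec, parameter, grid[i], br)
      st <- pt$state
      vals[[i]] <- data.frame(parameter = parameter, value = grid[i],
                              branch = br, Pa = pt$Pa, P_inf = pt$P_inf,
                              converged = pt$converged)
    }
    rows <- c(rows, vals)
  }
  out <- do.call(rbind, rows)
  class(out) <- c("scan_result", class(out))
  attr(out, "spec") <- spec
  out
}

#' Classify a precomputed scan curve
#'
#' Grid-resolution classification of a P_inf curve (no solver refinement):
#' used for simulated branches and as a coarse first pass. A transition is a
#' jump when an adjacent-point difference (taken in the direction of
#' increasing connectivity) reaches `jump_delta`; it is continuous when the
#' curve crosses `onset_eps` without such a jump.
#'
#' @param grid Parameter values (sorted increasing).
#' @param values P_inf per grid point.
#' @param parameter Parameter name (sets the connectivity direction).
#' @param onset_eps Threshold below which P_inf counts as zero.
#' @param jump_delta Minimum discontinuity size.
#' @return A `transition_report`.
#' @export
classify_curve <- function(grid, values, parameter = "mean_degree",
                           onset_eps = 1e-6, jump_delta = 1e-3) {
  dirn <- param_direction(parameter)
  v <- if (dirn > 0) values else rev(values)
  g <- if (dirn > 0) grid else rev(grid)
  d <- diff(v)
  i <- which.max(d)
  onset_idx <- which(v > onset_eps)[1L]
  if (length(d) == 0L || d[i] < jump_delta) {
    type <- if (is.na(onset_idx)) "none" else "continuous"
    kci <- if (!is.na(onset_idx) && onset_idx > 1L)
      (g[onset_idx - 1L] + g[onset_idx]) / 2 else NA_real_
    return(new_transition_report(type, kcI = kci, kcII = NA_real_,
                                 jump_height = 0, onset_eps = onset_eps,
                                 jump_delta = jump_delta,
                                 bisection_tol = NA_real_))
  }
  below <- v[i]
  type <- if (below < onset_eps) "first_order" else "hybrid"
  kci <- if (type == "hybrid" && !is.na(onset_idx) && onset_idx > 1L)
    (g[onset_idx - 1L] + g[onset_idx]) / 2 else NA_real_
  kcii <- (g[i] + g[i + 1L]) / 2
  if (type == "first_order") kci <- kcii
  new_transition_report(type, kcI = kci, kcII = kcii,
                        jump_height = d[i], onset_eps = onset_eps,
                        jump_delta = jump_delta, bisection_tol = NA_real_)
}

new_transition_report <- function(type, kcI, kcII, jump_height,
                                  onset_eps, jump_delta, bisection_tol,
                                  P_below = NA_real_, P_above = NA_real_,
                                  spinodal_kstar = NA_real_) {
  structure(
    list(type = type, kcI = kcI, kcII = kcII, jump_height = jump_height,
         P_below = P_below, P_above = P_above,
         spinodal_kstar = spinodal_kstar,
         onset_eps = onset_eps, jump_delta = jump_delta,
         bisection_tol = bisection_tol),
    class = "transition_report")
}

#' @export
print.transition_report <- function(x, ...) {
  cat(sprintf("<transition_report> type=%s", x$type))
  if (!is.na(x$kcI)) cat(sprintf(" kcI=%.6g", x$kcI))
  if (!is.na(x$kcII)) cat(sprintf(" kcII=%.6g (jump %.4g)", x$kcII,
                                  x$jump_height))
  if (!is.na(x$spinodal_kstar)) cat(sprintf(" k*=%.6g", x$spinodal_kstar))
  cat("\n")
  invisible(x)
}

# Locate a discontinuity of `f` inside the adjacent-gap bracket [a, b] by
# bisection on the mid-height threshold; returns the refined bracket and the
# curve values on its two sides.
bisect_jump <- function(f, a, b, va, vb, tol) {
  thr <- (va + vb) / 2
  while (b - a > tol) {
    mid <- (a + b) / 2
    vm <- f(mid)
    if (vm > thr) { b <- mid; vb <- vm } else { a <- mid; va <- vm }
  }
  list(lo = a, hi = b, below = va, above = vb)
}

# Bisection on the predicate f(x) > eps.
bisect_onset <- function(f, a, b, tol, eps) {
  while (b - a > tol) {
    mid <- (a + b) / 2
    if (f(mid) > eps) b <- mid else a <- mid
  }
  (a + b) / 2
}

#' Classify the phase transition of the theory along a parameter
#'
#' Scans P_inf on a grid across `bracket` (cold-started solves, so each point
#' is the branch's deterministic fixed point), locates the largest
#' discontinuity by bisection refined to `bisection_tol`, and locates the
#' continuous onset kcI by bisection on P_inf > `onset_eps`. The transition
#' is `"hybrid"` when a jump of at least `jump_delta` is preceded by a
#' nonzero continuous branch (P_inf just below the jump at least
#' `onset_eps`), `"first_order"` when P_inf jumps directly from (numerical)
#' zero, `"continuous"` when P_inf crosses `onset_eps` without any jump, and
#' `"none"` otherwise. For `parameter = "gamma"` the connectivity direction
#' is reversed and the jump is sought in decreasing gamma.
#'
#' @inheritParams scan_parameter
#' @param bracket Length-2 numeric range containing the transition region.
#' @param onset_eps Threshold below which P_inf counts as zero.
#' @param jump_delta Minimum discontinuity size.
#' @param bisection_tol Parameter resolution of the bisections.
#' @param grid_points Coarse-grid size for the first pass.
#' @param branch Branch to classify (`"lower"` = growth).
#' @param find_spinodal If TRUE, also locate the upper-branch fold k* (the
#'   spinodal: the connectivity below which the upper branch collapses onto
#'   the lower branch).
#' @return A `transition_report` with fields `type`, `kcI`, `kcII`,
#'   `jump_height`, `P_below`, `P_above`, `spinodal_kstar` and the
#'   tolerances used.
#' @export
classify_transition <- function(spec, parameter, bracket,
                                onset_eps = 1e-6, jump_delta = 1e-3,
                                bisection_tol = 1e-6, grid_points = 41L,
                                branch = "lower", find_spinodal = FALSE) {
  check_parameter(spec, parameter)
  stopifnot(length(bracket) == 2L, bracket[1L] < bracket[2L])
  f_raw <- function(v) solve_point(spec, parameter, v, branch)$P_inf
  dirn <- param_direction(parameter)
  # work on a connectivity axis where P_inf is nondecreasing
  tf <- function(v) if (dirn > 0) v else -v
  f <- function(u) f_raw(if (dirn > 0) u else -u)
  lo <- min(tf(bracket)); hi <- max(tf(bracket))
  grid <- seq(lo, hi, length.out = grid_points)
  vals <- vapply(grid, f, numeric(1))

  d <- diff(vals)
  i <- which.max(d)
  jump <- NULL
  if (d[i] >= jump_delta) {
    jump <- bisect_jump(f, grid[i], grid[i + 1L], vals[i], vals[i + 1L],
                        bisection_tol)
    if (jump$above - jump$below < jump_delta) jump <- NULL
  }

  onset_idx <- which(vals > onset_eps)[1L]
  kstar <- NA_real_
  if (find_spinodal) {
    fu <- function(u) solve_point(spec, parameter,
                                  if (dirn > 0) u else -u, "upper")$P_inf
    gap <- function(u) fu(u) - f(u)
    gv <- vapply(grid, gap, numeric(1))
    j <- which(gv > jump_delta)[1L]
    if (!is.na(j) && j > 1L)
      kstar <- tf(bisect_onset(gap, grid[j - 1L], grid[j], bisection_tol,
                               jump_delta))
  }

  if (is.null(jump)) {
    if (is.na(onset_idx) || onset_idx == 1L) {
      type <- if (is.na(onset_idx)) "none" else "continuous"
      kci <- if (type == "continuous") NA_real_ else NA_real_
      return(new_transition_report(type, kcI = kci, kcII = NA_real_,
                                   jump_height = 0, onset_eps, jump_delta,
                                   bisection_tol, spinodal_kstar = kstar))
    }
    kci <- tf(bisect_onset(f, grid[onset_idx - 1L], grid[onset_idx],
                           bisection_tol, onset_eps))
    return(new_transition_report("continuous", kcI = kci, kcII = NA_real_,
                                 jump_height = 0, onset_eps, jump_delta,
                                 bisection_tol, spinodal_kstar = kstar))
  }

  kcii <- tf((jump$lo + jump$hi) / 2)
  if (jump$below >= onset_eps) {
    # continuous onset precedes the jump: locate kcI below the jump
    kci <- if (!is.na(onset_idx) && onset_idx > 1L &&
                 grid[onset_idx - 1L] < jump$lo)
      tf(bisect_onset(f, grid[onset_idx - 1L], min(grid[onset_idx], jump$lo),
                      bisection_tol, onset_eps))
    else NA_real_
    return(new_transition_report("hybrid", kcI = kci, kcII = kcii,
                                 jump_height = jump$above - jump$below,
                                 onset_eps, jump_delta, bisection_tol,
                                 P_below = jump$below, P_above = jump$above,
                                 spinodal_kstar = kstar))
  }
  new_transition_report("first_order", kcI = kcii, kcII = kcii,
                        jump_height = jump$above - jump$below,
                        onset_eps, jump_delta, bisection_tol,
                        P_below = jump$below, P_above = jump$above,
                        spinodal_kstar = kstar)
}

# Measure the largest lower-branch discontinuity inside `bracket`; returns
# NULL when no adjacent gap reaches jump_delta.
measure_jump <- function(spec, parameter, bracket, jump_delta = 1e-3,
                         bisection_tol = 1e-6, grid_points = 41L) {
  dirn <- param_direction(parameter)
  f <- function(u) solve_point(spec, parameter,
                               if (dirn > 0) u else -u, "lower")$P_inf
  lo <- min(dirn * bracket); hi <- max(dirn * bracket)
  grid <- seq(lo, hi, length.out = grid_points)
  vals <- vapply(grid, f, numeric(1))
  d <- diff(vals)
  i <- which.max(d)
  if (d[i] < jump_delta) return(NULL)
  jump <- bisect_jump(f, grid[i], grid[i + 1L], vals[i], vals[i + 1L],
                      bisection_tol)
  if (jump$above - jump$below < jump_delta) return(NULL)
  list(kcII = dirn * (jump$lo + jump$hi) / 2,
       below = jump$below, above = jump$above,
       height = jump$above - jump$below)
}

#' Critical initial fraction q* between continuous and hybrid regimes
#'
#' Bisects on the existence of a lower-branch jump (of at least
#' `jump_delta`) in the connectivity scan: below q* the transition is hybrid
#' (a jump exists), above q* it is continuous, and the jump height vanishes
#' as q approaches q* from below.
#'
#' @inheritParams classify_transition
#' @param q_bracket Length-2 range straddling q* (jump present at the low
#'   end, absent at the high end).
#' @param scan_bracket Connectivity bracket containing the jump for every q
#'   in `q_bracket`.
#' @param tol Resolution of the q bisection.
#' @return q* as a single number, with the bracketing diagnostics as
#'   attributes.
#' @export
find_critical_q <- function(spec, q_bracket, scan_bracket,
                            parameter = if (spec$family == "er")
                              "mean_degree" else "gamma",
                            jump_delta = 1e-3, tol = 1e-3,
                            bisection_tol = 1e-6) {
  check_parameter(spec, parameter)
  has_jump <- function(q) {
    sp <- spec; sp$q <- q
    !is.null(measure_jump(sp, parameter, scan_bracket,
                          jump_delta = jump_delta,
                          bisection_tol = bisection_tol,
                          grid_points = 21L))
  }
  a <- q_bracket[1L]; b <- q_bracket[2L]
  if (!has_jump(a))
    stop("no jump at the low end of `q_bracket`; bracket does not straddle q*")
  if (has_jump(b))
    stop("jump persists at the high end of `q_bracket`; bracket does not straddle q*")
  while (b - a > tol) {
    mid <- (a + b) / 2
    if (has_jump(mid)) a <- mid else b <- mid
  }
  structure((a + b) / 2, lower = a, upper = b)
}

#' Jump-point location and jump height as functions of q
#'
#' For each q in `q_grid`, locates the lower-branch jump point kcII in the
#' connectivity parameter and records P_inf on both sides. The giant
#' component of the lower branch evaluated at the jump point, P_inf(kcII),
#' grows as a power of q below q*, so an ordinary least-squares fit of
#' log P_inf(kcII) (the `P_below` column) against log q is returned together
#' with its R^2.
#'
#' @inheritParams find_critical_q
#' @param q_grid Values of q, all below q*.
#' @return List with `records` (data frame: q, kcII, P_below, P_above,
#'   height), `exponent`, `intercept`, `r_squared`.
#' @export
jump_height_curve <- function(spec, q_grid, scan_bracket,
                              parameter = if (spec$family == "er")
                                "mean_degree" else "gamma",
                              jump_delta = 1e-3, bisection_tol = 1e-6) {
  check_parameter(spec, parameter)
  recs <- lapply(q_grid, function(q) {
    sp <- spec; sp$q <- q
    j <- measure_jump(sp, parameter, scan_bracket, jump_delta = jump_delta,
                      bisection_tol = bisection_tol)
    if (is.null(j)) {
      warning(sprintf("no jump found at q = %g (above q*?); point excluded",
                      q))
      return(NULL)
    }
    data.frame(q = q, kcII = j$kcII, P_below = j$below, P_above = j$above,
               height = j$height)
  })
  records <- do.call(rbind, recs)
  if (is.null(records) || nrow(records) < 2L)
    stop("fewer than two q values produced a jump; cannot fit")
  fit <- stats::lm(log(P_below) ~ log(q), data = records)
  list(records = records,
       exponent = unname(stats::coef(fit)[2L]),
       intercept = unname(stats::coef(fit)[1L]),
       r_squared = summary(fit)$r.squared)
}

#' Growth-versus-retention hysteresis loop
#'
#' The forward branch is the lower-branch (growth) theory scan, classified
#' with [classify_transition()]. The reverse branch is the retention
#' process, computed either as the `"upper"` branch of the same equations
#' (the analytic greatest fixed point; a faithful description of retention
#' on directed locally tree-like networks, where reciprocal links are
#' vanishingly rare) or by `"simulation"` of the retention cascade on
#' sampled networks with the q-fraction of seeds pinned (required for
#' undirected networks, where retention is additionally sustained by mutual
#' support between adjacent active nodes -- an effect outside the growth
#' equations; see the package vignette). `"auto"` picks `"upper"` for
#' directed and `"simulation"` for undirected specs. Simulated reverse
#' branches are classified at grid resolution with noise-tolerant
#' thresholds `sim_onset_eps` and `sim_jump_delta`.
#'
#' @inheritParams classify_transition
#' @param grid Sorted connectivity grid for both branches.
#' @param reverse_method `"auto"`, `"upper"`, or `"simulation"`.
#' @param sim_n Nodes per sampled network for the simulated reverse branch.
#' @param sim_onset_eps,sim_jump_delta Grid-resolution classification
#'   thresholds for the simulated branch.
#' @param seed Seed for the simulated reverse branch.
#' @return A `hysteresis_result`: `forward` and `reverse` (each a list with
#'   `scan` and `report`), `loop_gap` (max pointwise reverse - forward),
#'   `reverse_method`.
#' @export
hysteresis_loop <- function(spec, grid,
                            parameter = if (spec$family == "er")
                              "mean_degree" else "gamma",
                            reverse_method = c("auto", "upper", "simulation"),
                            onset_eps = 1e-6, jump_delta = 1e-3,
                            bisection_tol = 1e-6,
                            sim_n = 20000L, sim_onset_eps = 1e-3,
                            sim_jump_delta = 0.1, seed = NULL) {
  reverse_method <- match.arg(reverse_method)
  if (reverse_method == "auto")
    reverse_method <- if (spec$directed) "upper" else "simulation"
  check_parameter(spec, parameter)
  bracket <- range(grid)

  fwd_scan <- scan_parameter(spec, parameter, grid, branch = "lower",
                             warm_start = FALSE)
  fwd_rep <- classify_transition(spec, parameter, bracket,
                                 onset_eps = onset_eps,
                                 jump_delta = jump_delta,
                                 bisection_tol = bisection_tol)

  if (reverse_method == "upper") {
    rev_scan <- scan_parameter(spec, parameter, grid, branch = "upper",
                               warm_start = FALSE)
    rev_rep <- classify_transition(spec, parameter, bracket,
                                   onset_eps = onset_eps,
                                   jump_delta = jump_delta,
                                   bisection_tol = bisection_tol,
                                   branch = "upper")
  } else {
    base_seed <- if (is.null(seed)) 1L else as.integer(seed)
    sim_point <- function(v) {
      sp <- spec; sp[[parameter]] <- v
      pseed <- (base_seed * 7919 + round(v * 1e7)) %% 2000000011 + 1
      g <- sample_model_graph(sp, sim_n, pseed)
      init <- seed_states(g, sp$q, pseed + 17L)
      res <- run_retention(g, which(init == 1L) - 1L, sp$m)
      comp <- components_active(g, res$final_states)
      c(res$active_fraction,
        if (sp$directed) comp$gout_fraction else comp$gcc_fraction)
    }
    gv <- grid
    sims <- vapply(gv, sim_point, numeric(2))
    pa <- sims[1L, ]; pinf <- sims[2L, ]
    # a genuine discontinuity survives grid halving; a steep continuous
    # onset has adjacent differences that shrink with the spacing, so
    # refine around every candidate jump before accepting it
    for (lvl in 1:3) {
      big <- which(abs(diff(pinf)) >= sim_jump_delta)
      if (length(big) == 0L) break
      mids <- (gv[big] + gv[big + 1L]) / 2
      mids <- setdiff(mids, gv)
      if (length(mids) == 0L) break
      msims <- vapply(mids, sim_point, numeric(2))
      ord <- order(c(gv, mids))
      pa <- c(pa, msims[1L, ])[ord]
      pinf <- c(pinf, msims[2L, ])[ord]
      gv <- c(gv, mids)[ord]
    }
    rev_scan <- data.frame(parameter = parameter, value = gv,
                           branch = "retention_sim", Pa = pa, P_inf = pinf,
                           converged = TRUE)
    class(rev_scan) <- c("scan_result", class(rev_scan))
    rev_rep <- classify_curve(gv, pinf, parameter,
                              onset_eps = sim_onset_eps,
                              jump_delta = sim_jump_delta)
  }
  fwd_v <- fwd_scan$P_inf
  rev_v <- rev_scan$P_inf[match(fwd_scan$value, rev_scan$value)]
  structure(
    list(forward = list(scan = fwd_scan, report = fwd_rep),
         reverse = list(scan = rev_scan, report = rev_rep),
         loop_gap = max(rev_v - fwd_v),
         reverse_method = reverse_method),
    class = "hysteresis_result")
}

#' @export
print.hysteresis_result <- function(x, ...) {
  cat(sprintf(
    "<hysteresis_result> forward %s, reverse %s (%s), loop gap %.4g\n",
    x$forward$report$type, x$reverse$report$type, x$reverse_method,
    x$loop_gap))
  invisible(x)
}

#' Transition-type taxonomy across network families
#'
#' Classifies the growth transition for a battery of parameter settings in
#' each network family and reports which transition types occur. The default
#' settings cover, per family, a weakly seeded scan (small q), an
#' intermediate one, and a strongly seeded one, using the connectivity
#' parameter natural to the family (mean degree for ER, q for SF at fixed
#' gamma). The hybrid/first-order boundary is drawn at the resolution of a
#' finite reference system: a predicted giant component holding fewer than
#' ~10 nodes at `n_ref` is not extensive, so jumps from such a state are
#' recorded as first-order (`onset_eps = 10 / n_ref`).
#'
#' @param families Character vector among `"directed_er"`, `"undirected_er"`,
#'   `"directed_sf"`, `"undirected_sf"`.
#' @param n_ref Reference system size setting the onset resolution.
#' @param jump_delta Minimum discontinuity size.
#' @param grid_points Coarse-grid size per classification.
#' @return Named list: per family, the sorted character vector of observed
#'   transition types, with the per-setting reports as attribute
#'   `"reports"`.
#' @export
table2_taxonomy <- function(families = c("directed_er", "undirected_er",
                                         "directed_sf", "undirected_sf"),
                            n_ref = 1e5, jump_delta = 1e-3,
                            grid_points = 31L) {
  onset_eps <- 10 / n_ref
  er_settings <- list(
    list(q = 0.05, m = 2, bracket = c(0.3, 6)),
    list(q = 0.10, m = 2, bracket = c(0.3, 6)),
    list(q = 0.30, m = 2, bracket = c(0.3, 6)),
    list(q = 0.10, m = 3, bracket = c(0.3, 8)))
  sf_settings <- list(
    list(gamma = 2.5, m = 2, bracket = c(0.005, 0.35)),   # weak hubs
    list(gamma = 2.0, m = 2, bracket = c(0.005, 0.12)),   # moderate hubs
    list(gamma = 3.0, m = 2, bracket = c(0.01, 0.30)),
    list(gamma = 1.3, m = 2, bracket = c(5e-5, 0.02)),    # strong hubs
    list(gamma = 1.8, m = 2, bracket = c(5e-5, 0.01)),
    list(gamma = 2.5, m = 4, bracket = c(0.002, 0.08)))
  out <- list()
  for (fam in families) {
    directed <- startsWith(fam, "directed")
    family <- if (endsWith(fam, "er")) "er" else "sf"
    settings <- if (family == "er") er_settings else sf_settings
    reports <- lapply(settings, function(s) {
      if (family == "er") {
        sp <- model_spec("er", directed, q = s$q, m = s$m, mean_degree = 1)
        classify_transition(sp, "mean_degree", s$bracket,
                            onset_eps = onset_eps, jump_delta = jump_delta,
                            grid_points = grid_points)
      } else {
        sp <- model_spec("sf", directed, q = 0.5, m = s$m, gamma = s$gamma)
        classify_transition(sp, "q", s$bracket,
                            onset_eps = onset_eps, jump_delta = jump_delta,
                            grid_points = grid_points)
      }
    })
    types <- sort(unique(vapply(reports, function(r) r$type, character(1))))
    types <- setdiff(types, "none")
    out[[fam]] <- structure(types, reports = reports)
  }
  out
}

#' Write a scan result as CSV
#'
#' Columns `parameter`, `value`, `branch`, `Pa`, `P_inf`, `converged`, at
#' full double precision.
#'
#' @param scan A `scan_result`.
#' @param path Output file path.
#' @export
write_scan_csv <- function(scan, path) {
  df <- as.data.frame(scan)
  for (cl in c("Pa", "P_inf"))
    df[[cl]] <- sprintf("%.15g", df[[cl]])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(scan)
}

#' Serialize a transition or hysteresis report to JSON
#'
#' @param report A `transition_report` or `hysteresis_result`.
#' @param path Optional output path; when NULL the JSON string is returned.
#' @export
report_to_json <- function(report, path = NULL) {
  rec <- if (inherits(report, "hysteresis_result"))
    list(record = "hysteresis_result",
         forward = c(unclass(report$forward$report),
                     list(scan = as.data.frame(report$forward$scan))),
         reverse = c(unclass(report$reverse$report),
                     list(scan = as.data.frame(report$reverse$scan))),
         loop_gap = report$loop_gap,
         reverse_method = report$reverse_method)
  else c(list(record = "transition_report"), unclass(report))
  js <- jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA, na = "null")
  if (is.null(path)) js else { writeLines(js, path); invisible(js) }
}
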