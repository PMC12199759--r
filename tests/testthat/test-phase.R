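test_that("scans record both branches and respect monotonicity", {
  spec <- model_spec("er", FALSE, q = 0.1, m = 2, mean_degree = 1)
  # single-point scan equals a direct solver call
  one <- scan_parameter(spec, "mean_degree", 2.5)
  direct <- solve_undirected(poisson_degree_distribution(2.5), 0.1, 2)
  expect_equal(nrow(one), 1L)
  expect_equal(one$P_inf, direct$P_inf, tolerance = 1e-9)

  grid <- seq(0.5, 8, length.out = 16)
  sc <- scan_parameter(spec, "mean_degree", grid, branch = "both")
  expect_equal(nrow(sc), 32L)
  lower <- sc[sc$branch == "lower", ]
  upper <- sc[sc$branch == "upper", ]
  expect_true(all(diff(lower$P_inf) >= -1e-10))
  expect_true(all(upper$P_inf >= lower$P_inf - 1e-8))
  expect_true(all(sc$converged))

  # q = 1: branches coincide
  sp1 <- model_spec("er", FALSE, q = 1, m = 2, mean_degree = 1)
  sc1 <- scan_parameter(sp1, "mean_degree", c(1.5, 3), branch = "both")
  expect_lt(max(abs(sc1$P_inf[sc1$branch == "lower"] -
                      sc1$P_inf[sc1$branch == "upper"])), 1e-10)
})

test_that("jump bisection recovers a planted discontinuity", {
  # piecewise stub: continuous drift plus a jump of 0.2 at k = 3.7
  f <- function(k) 0.05 + 0.01 * k + 0.2 * (k >= 3.7)
  jump <- growthperc:::bisect_jump(f, 3, 4, f(3), f(4), 1e-6)
  expect_lt(abs((jump$lo + jump$hi) / 2 - 3.7), 1e-6)
  expect_equal(jump$above - jump$below, 0.2, tolerance = 1e-3)
})

test_that("curve classifier separates onset, jump, and their combination", {
  # at grid resolution a "jump" is an adjacent difference >= jump_delta, so
  # jump_delta must exceed slope * spacing for smooth curves
  g <- seq(1, 5, by = 0.1)
  cont <- pmax(0, 0.2 * (g - 2))
  expect_equal(classify_curve(g, cont, jump_delta = 0.1)$type, "continuous")
  hyb <- pmax(0, 0.05 * (g - 2)) + 0.4 * (g >= 4)
  rh <- classify_curve(g, hyb, jump_delta = 0.1)
  expect_equal(rh$type, "hybrid")
  expect_equal(rh$kcII, 3.95, tolerance = 0.1)
  fo <- 0.5 * (g >= 3.5)
  expect_equal(classify_curve(g, fo, jump_delta = 0.1)$type, "first_order")
  expect_equal(classify_curve(g, rep(0, length(g)))$type, "none")
})

test_that("ER transitions classify as hybrid with ordered critical points", {
  spec <- model_spec("er", TRUE, q = 0.1, m = 2, mean_degree = 1)
  rep_ <- classify_transition(spec, "mean_degree", c(0.5, 4),
                              find_spinodal = TRUE)
  expect_equal(rep_$type, "hybrid")
  expect_lt(rep_$kcI, rep_$kcII)
  expect_gte(rep_$P_below, rep_$onset_eps)
  expect_gte(rep_$jump_height, rep_$jump_delta)
  # the spinodal (upper-branch fold) precedes the lower-branch jump
  expect_lt(rep_$spinodal_kstar, rep_$kcII)

  # classification is stable under halving the bisection tolerance
  rep2 <- classify_transition(spec, "mean_degree", c(0.5, 4),
                              bisection_tol = 5e-7)
  expect_equal(rep2$type, rep_$type)
  expect_lt(abs(rep2$kcII - rep_$kcII), 2e-6)

  # large q: continuous, with kcI close to a dense-grid onset
  spc <- model_spec("er", TRUE, q = 0.4, m = 2, mean_degree = 1)
  repc <- classify_transition(spc, "mean_degree", c(0.5, 4))
  expect_equal(repc$type, "continuous")
  dense <- seq(0.5, 4, by = 1e-3)
  pv <- vapply(dense, function(k)
    solve_directed(er_joint(k), 0.4, 2)$P_inf, 0)
  onset_dense <- dense[which(pv > 1e-6)[1L]]
  expect_lt(abs(repc$kcI - onset_dense), 5e-3)
})

test_that("directed and undirected ER jump points nearly coincide", {
  for (q in c(0.08, 0.1, 0.15)) {
    jd <- growthperc:::measure_jump(
      model_spec("er", TRUE, q = q, m = 2, mean_degree = 1),
      "mean_degree", c(1.5, 5))
    ju <- growthperc:::measure_jump(
      model_spec("er", FALSE, q = q, m = 2, mean_degree = 1),
      "mean_degree", c(1.5, 5))
    expect_lt(abs(jd$kcII - ju$kcII), 0.05)
  }
})

test_that("critical q* bisection matches a dense grid scan", {
  spec <- model_spec("er", TRUE, q = 0.1, m = 2, mean_degree = 1)
  qs <- find_critical_q(spec, q_bracket = c(0.1, 0.3),
                        scan_bracket = c(1, 6), tol = 1e-3)
  # jump present just below, absent just above
  expect_false(is.null(growthperc:::measure_jump(
    model_spec("er", TRUE, q = qs - 0.01, m = 2, mean_degree = 1),
    "mean_degree", c(1, 6), grid_points = 21L)))
  expect_null(growthperc:::measure_jump(
    model_spec("er", TRUE, q = qs + 0.01, m = 2, mean_degree = 1),
    "mean_degree", c(1, 6), grid_points = 21L))
  # grid oracle at resolution 1e-3 over a narrow window
  qgrid <- seq(qs - 5e-3, qs + 5e-3, by = 1e-3)
  has <- vapply(qgrid, function(q) !is.null(growthperc:::measure_jump(
    model_spec("er", TRUE, q = q, m = 2, mean_degree = 1),
    "mean_degree", c(1, 6), grid_points = 21L)), TRUE)
  boundary <- qgrid[which(!has)[1L]]
  expect_lt(abs(qs - boundary), 2e-3)
  expect_error(find_critical_q(spec, q_bracket = c(0.3, 0.4),
                               scan_bracket = c(1, 6)), "straddle")
})
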