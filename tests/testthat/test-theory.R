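test_that("binomial term matches exhaustive outcome enumeration", {
  expect_equal(binomial_term(0.5, 2, 1), 0.5)
  # normalization for arbitrary (p, n)
  for (p in c(0, 0.3, 0.77, 1))
    expect_equal(sum(binomial_term(p, 20, 0:20)), 1, tolerance = 1e-12)
  # enumeration oracle at small n: sum the probability of every outcome
  # string with exactly s successes
  enum <- function(p, n, s) {
    total <- 0
    for (code in 0:(2^n - 1)) {
      bits <- as.integer(intToBits(code))[1:n]
      if (sum(bits) == s) total <- total + prod(ifelse(bits == 1, p, 1 - p))
    }
    total
  }
  for (s in c(0, 3, 7, 12))
    expect_equal(binomial_term(0.3, 12, s), enum(0.3, 12, s),
                 tolerance = 1e-12)
  expect_error(binomial_term(0.5, 5, 7), "0..n")
})

test_that("closed-form kernel equals the explicit t-sum", {
  expect_equal(h_closed(0.4, 0, 0, 5), 0)
  expect_equal(h_closed(0.4, 0.3, 0.2, 0), 0)
  set.seed(1)
  for (i in 1:1000) {
    y <- stats::runif(1, 0.05, 0.95)
    yi <- stats::runif(1, 0, y)
    xi <- stats::runif(1, yi, min(1, yi + (1 - y)))
    k <- sample(0:12, 1)
    expect_equal(h_closed(y, xi, yi, k), oracle_h_tsum(y, xi, yi, k),
                 tolerance = 1e-10)
  }
})

test_that("stage-2 per-degree closed forms equal their explicit t-sums", {
  set.seed(2)
  for (i in 1:1000) {
    a <- rand_stage2_args()
    s <- sample(0:12, 1)
    ks <- sample(0:12, 1)
    expect_equal(closed_eq13(s, a$x, a$y, a$be, a$ga),
                 oracle_eq13_tsum(s, a$x, a$y, a$be, a$ga),
                 tolerance = 1e-9)
    expect_equal(closed_eq14(s, ks, a$x, a$y, a$al, a$be, a$ga),
                 oracle_eq14_tsum(s, ks, a$x, a$y, a$al, a$be, a$ga),
                 tolerance = 1e-9)
  }
})

test_that("one stage-2 update equals a brute-force t-sum update", {
  # the production update assembles the closed forms into weighted sums
  # over the degree distribution; rebuild it from the raw t-sums
  oracle_step2 <- function(al, be, ga, x, y, k, w, q, m) {
    aln <- 0; ben_in <- 0; gan <- 0
    rb <- if (x < 1e-14) 0 else be / x
    D <- 1 - (if (1 - x < 1e-14) 0 else (al - be) / (1 - x))
    for (j in seq_along(k)) {
      n1 <- k[j] - 1
      a_j <- b_j <- g_j <- 0
      for (s in 0:n1) {
        Fs <- stats::dbinom(s, n1, x)
        a_term <- if (s <= m - 2) 1 - (1 - rb)^s
        else 1 - (1 - rb)^s * D^(n1 - s)
        a_j <- a_j + Fs * a_term
        b_term <- if (s <= m - 2) oracle_eq13_tsum(s, x, y, be, ga)
        else oracle_eq14_tsum(s, n1 - s, x, y, al, be, ga)
        b_j <- b_j + Fs * b_term
        if (s >= m)
          g_j <- g_j + Fs * (q * (1 - (1 - rb)^s * D^(n1 - s)) +
                               (1 - q) * oracle_eq14_tsum(s, n1 - s, x, y,
                                                          al, be, ga))
      }
      aln <- aln + w[j] * a_j
      ben_in <- ben_in + w[j] * b_j
      gan <- gan + w[j] * g_j
    }
    c(aln, q * aln + (1 - q) * ben_in, gan)
  }
  set.seed(3)
  d <- poisson_degree_distribution(2.5, 1e-8)
  kk <- d$support[d$support >= 1]
  w <- (d$support * d$mass)[d$support >= 1]
  w <- w / sum(w)
  for (i in 1:20) {
    a <- rand_stage2_args()
    m <- sample(1:4, 1)
    q <- stats::runif(1)
    got <- growthperc:::step2_undirected(a$al, a$be, a$ga, a$x, a$y,
                                         kk, w, q, m)
    want <- oracle_step2(a$al, a$be, a$ga, a$x, a$y, kk, w, q, m)
    expect_equal(got, pmin(pmax(want, 0), 1), tolerance = 1e-9)
  }
})

test_that("undirected solver honours limits and invariants", {
  d <- poisson_degree_distribution(2)
  z <- solve_undirected(d, 0, 2)
  expect_equal(z$Pa_hat, 0)
  expect_equal(z$P_inf, 0)
  expect_equal(z$x_t, 0)

  # q = 1: classical giant component S = 1 - exp(-<k> S)
  s1 <- solve_undirected(d, 1, 3)
  S <- stats::uniroot(function(S) S - 1 + exp(-2 * S), c(1e-9, 1),
                      tol = 1e-12)$root
  expect_equal(s1$P_inf, S, tolerance = 1e-8)
  expect_equal(s1$Pa_hat, 1)

  sol <- solve_undirected(d, 0.3, 2)
  expect_true(sol$converged)
  expect_lte(sol$y_t, sol$x_t)
  expect_gte(sol$Pa_hat, 0.3)
  expect_lte(sol$P_inf, sol$Pa_hat + 1e-9)
  expect_lte(sol$gamma_v, sol$beta + 1e-12)
  expect_lte(sol$beta, sol$alpha + 1e-12)
})

test_that("lower-branch iteration is monotone and below the upper branch", {
  d <- poisson_degree_distribution(3)
  tr <- attr(solve_undirected(d, 0.15, 2, trace = TRUE, max_iter = 2000),
             "trace")
  expect_true(all(diff(tr[, "x"]) >= -1e-14))
  expect_true(all(diff(tr[, "y"]) >= -1e-14))
  for (k in c(2.3, 2.6, 3.2)) {
    lo <- solve_undirected(poisson_degree_distribution(k), 0.1, 2, "lower")
    up <- solve_undirected(poisson_degree_distribution(k), 0.1, 2, "upper")
    expect_gte(up$x_t, lo$x_t - 1e-10)
    expect_gte(up$y_t, lo$y_t - 1e-10)
    expect_gte(up$P_inf, lo$P_inf - 1e-10)
  }
  # lower-branch Pa and P_inf nondecreasing in q and in <k>
  pa_q <- vapply(seq(0.1, 0.9, 0.2), function(q)
    solve_undirected(d, q, 2)$Pa_hat, 0)
  expect_true(all(diff(pa_q) > 0))
  pi_k <- vapply(c(1, 2, 3, 4), function(k)
    solve_undirected(poisson_degree_distribution(k), 0.3, 2)$P_inf, 0)
  expect_true(all(diff(pi_k) >= 0))
})

test_that("compiled stage-1 loop agrees with the reference R iteration", {
  d <- powerlaw_degree_distribution(2.5, 1, 40)
  for (q in c(0.05, 0.4)) for (m in c(1, 3)) {
    fast <- solve_undirected(d, q, m)
    slow <- solve_undirected(d, q, m, trace = TRUE)
    expect_equal(fast$x_t, slow$x_t, tolerance = 1e-9)
    expect_equal(fast$y_t, slow$y_t, tolerance = 1e-9)
  }
  j <- er_joint(2.2)
  fast <- solve_directed(j, 0.12, 2)
  slow <- solve_directed(j, 0.12, 2, trace = TRUE)
  expect_equal(fast$Pa, slow$Pa, tolerance = 1e-9)
})

test_that("directed solver matches simulation in the fully seeded limit", {
  j <- er_joint(2)
  z <- solve_directed(j, 0, 2)
  expect_equal(z$Pa, 0)
  expect_equal(z$P_inf, 0)
  s1 <- solve_directed(j, 1, 4)
  expect_equal(s1$Pa, 1)
  # at q = 1 the GOUT is the classical directed giant out-component:
  # compare against one large simulated network
  g <- sample_er(100000, 2, directed = TRUE, seed = 31)
  comp <- components_active(g, rep.int(1L, g$n))
  expect_lt(abs(s1$P_inf - comp$gout_fraction), 0.01)
  # field ordering invariants
  sol <- solve_directed(j, 0.3, 2)
  expect_lte(sol$y, sol$x)
  expect_lte(sol$y_inf, sol$y + 1e-10)
  expect_lte(sol$y_inf, sol$x_inf + 1e-10)
  expect_gte(sol$Pa, 0.3)
  expect_lte(sol$P_inf, sol$Pa + 1e-9)
})

test_that("solutions serialize to JSON and back without loss", {
  sol <- solve_undirected(poisson_degree_distribution(2), 0.3, 2)
  js <- solution_to_json(sol)
  rec <- jsonlite::fromJSON(js)
  expect_equal(rec$Pa_hat, sol$Pa_hat, tolerance = 1e-15)
  expect_equal(rec$P_inf, sol$P_inf, tolerance = 1e-15)
  expect_equal(rec$type, "undirected_solution")
})
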