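test_that("seeding is Bernoulli(q) and reproducible", {
  g <- sample_er(10, 0, seed = 1)
  expect_identical(seed_states(g, 0, 1), rep.int(0L, 10))
  expect_identical(seed_states(g, 1, 1), rep.int(1L, 10))
  big <- sample_er(100000, 0, seed = 1)
  s <- seed_states(big, 0.3, 42)
  se3 <- 3 * sqrt(0.3 * 0.7 / big$n)
  expect_lt(abs(mean(s) - 0.3), se3)
  expect_identical(seed_states(big, 0.3, 42), s)
  expect_error(seed_states(g, 1.2), "0, 1")
})

test_that("induced index agrees with exhaustive enumeration", {
  for (seed in 1:10) {
    g <- rand_graph(10, 0.25, directed = TRUE, seed = seed)
    states <- seed_states(g, 0.5, seed + 100)
    for (v in 0:9)
      expect_identical(induced_index(g, states, v),
                       oracle_induced_index(g, states, v))
  }
  # undirected: "incoming neighbours" means neighbours
  gu <- rand_graph(10, 0.3, directed = FALSE, seed = 3)
  st <- seed_states(gu, 0.6, 5)
  for (v in 0:9)
    expect_identical(induced_index(gu, st, v),
                     oracle_induced_index(gu, st, v))
  # no active in-neighbour: undefined
  g2 <- growthperc:::new_netgraph(3, TRUE, rbind(c(0L, 1L)))
  expect_true(is.na(induced_index(g2, c(0L, 0L, 0L), 1L)))
  expect_error(induced_index(g2, c(0L, 0L, 0L), 5L), "node")
})

test_that("growth cascade equals the full-sweep oracle on random digraphs", {
  for (seed in 1:50) {
    n <- 50
    g <- rand_graph(n, 0.06, directed = TRUE, seed = seed)
    init <- seed_states(g, 0.3, seed + 500)
    m <- sample(0:3, 1)
    res <- run_growth(g, init, m)
    expect_identical(res$final_states, oracle_growth(g, init, m))
    # monotone: final dominates initial; active fraction exact
    expect_true(all(res$final_states >= init))
    expect_equal(res$active_fraction, sum(res$final_states) / n)
  }
})

test_that("m = 0 reduces to reachability from the seeds", {
  g <- growthperc:::new_netgraph(3, TRUE, rbind(c(0L, 1L), c(1L, 2L)))
  res <- run_growth(g, c(1L, 0L, 0L), 0)
  expect_identical(res$final_states, c(1L, 1L, 1L))
  # an isolated inactive node never self-activates
  g2 <- growthperc:::new_netgraph(2, TRUE, matrix(integer(0), 0, 2))
  expect_identical(run_growth(g2, c(1L, 0L), 0)$final_states, c(1L, 0L))
})

test_that("growth output is invariant under update order", {
  set.seed(99)
  for (gi in 1:20) {
    g <- rand_graph(30, 0.1, directed = TRUE, seed = gi + 40)
    init <- seed_states(g, 0.25, gi + 900)
    ref <- run_growth(g, init, 2)$final_states
    for (s in 1:5) {
      ord <- sample(g$n)
      expect_identical(oracle_growth(g, init, 2, order = ord), ref)
    }
  }
})

test_that("enlarging the seed set never shrinks the growth fixed point", {
  for (seed in 1:10) {
    g <- rand_graph(40, 0.08, directed = TRUE, seed = seed + 60)
    init <- seed_states(g, 0.2, seed + 700)
    bigger <- init
    extra <- which(init == 0L)
    if (length(extra)) bigger[extra[sample.int(length(extra), 1)]] <- 1L
    r1 <- run_growth(g, init, 2)$final_states
    r2 <- run_growth(g, bigger, 2)$final_states
    expect_true(all(r2 >= r1))
  }
})

test_that("retention matches its sweep oracle and dominates growth", {
  for (seed in 1:25) {
    g <- rand_graph(40, 0.08, directed = (seed %% 2 == 0), seed = seed)
    init <- seed_states(g, 0.3, seed + 300)
    pinned <- which(init == 1L) - 1L
    m <- sample(1:3, 1)
    ret <- run_retention(g, pinned, m)
    expect_identical(ret$final_states, oracle_retention(g, pinned, m))
    # greatest vs least fixed point of the same support predicate
    gro <- run_growth(g, init, m)
    expect_true(all(ret$final_states >= gro$final_states))
    expect_true(all(ret$final_states <= 1L),
                label = "retention states are binary")
    expect_true(all(ret$final_states[pinned + 1L] == 1L))
  }
  # pinned = all nodes: everything stays active
  g <- rand_graph(10, 0.2, directed = TRUE, seed = 5)
  expect_identical(run_retention(g, 0:9, 3)$final_states, rep.int(1L, 10))
})

test_that("growth fixed points are stable under the retention rule", {
  for (seed in 1:20) {
    g <- rand_graph(40, 0.1, directed = (seed %% 2 == 0), seed = seed + 20)
    init <- seed_states(g, 0.25, seed + 400)
    m <- 2
    fin <- run_growth(g, init, m)$final_states
    grown <- which(fin == 1L & init == 0L) - 1L
    for (v in grown) {
      mi <- induced_index(g, fin, v)
      expect_true(!is.na(mi) && mi >= m)
    }
  }
})

test_that("ensemble summaries are reproducible with exact SE bookkeeping", {
  spec <- model_spec("er", FALSE, q = 0.3, m = 2, mean_degree = 3)
  one <- simulate_ensemble(spec, 2000, 1, seed = 8)
  expect_equal(one$se_active, 0)
  expect_equal(one$mean_active, one$active_fraction[1])
  e1 <- simulate_ensemble(spec, 2000, 3, seed = 8)
  e2 <- simulate_ensemble(spec, 2000, 3, seed = 8)
  expect_identical(e1, e2)
  expect_equal(e1$se_active, stats::sd(e1$active_fraction) / sqrt(3))
})
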