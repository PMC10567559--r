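test_that("alpha = 1 cascade matches the Poisson closed form", {
  par <- selection_params(alpha = 1, k_d = 1.3)
  tg <- seq(0, 5 / 1.3, length.out = 11)
  tr <- integrate_growth(par, N1 = 50, t_grid = tg, a_max = 10)
  cf <- growth_closed_form(par, 50, tg, 10)
  sel <- cf > 0
  expect_lt(max(abs(tr$N[sel] - cf[sel]) / cf[sel]), 1e-6)
  expect_equal(tr$N[1, ], c(50, rep(0, 9)))  # t = 0 keeps initial condition
})

test_that("alpha = 0 with unit activation advances one level per 1/k_d", {
  par <- selection_params(alpha = 0, k_d = 1)
  tg <- seq(0, 6, 0.25)
  # discontinuous feed rates: moderate tolerances are the appropriate ones
  tr <- integrate_growth(par, N1 = 100, t_grid = tg, a_max = 8, activation = 1,
                         rtol = 1e-8, atol = 1e-8)
  for (a in 2:6) {
    expected <- pmax(0, tg - (a - 2))
    expect_lt(max(abs(tr$N[, a] - expected)), 0.05)
  }
})

test_that("growth parameters are validated", {
  expect_error(selection_params(alpha = 2), "alpha")
  expect_error(selection_params(k_d = 0), "k_d")
  expect_error(selection_params(k_p = -1), "k_p")
  expect_error(integrate_growth(selection_params(), N1 = 0, t_grid = 0:1), "N1")
  expect_error(integrate_growth(selection_params(), N1 = 1, t_grid = c(0, NA)),
               "non-finite")
  p <- selection_params(alpha = 0.5, k_d = 2, k_p = 4)
  expect_equal(p$tau_d, 0.5)
  expect_equal(p$tau_p, 0.25)
})

test_that("stochastic engine is seeded, reproducible, and respects event caps", {
  par <- selection_params(alpha = 1, k_d = 1)
  s0 <- stochastic_growth(par, seed = 3, N1 = 20, max_events = 0)
  expect_equal(s0$final_N[1], 20)
  expect_equal(sum(s0$final_N[-1]), 0)
  s1 <- stochastic_growth(par, seed = 3, N1 = 20, max_events = 200)
  s2 <- stochastic_growth(par, seed = 3, N1 = 20, max_events = 200)
  expect_identical(s1$final_N, s2$final_N)
  expect_equal(s1$events, 200L)
  # alpha = 1 means the whole pool is available: novel count equals unique growth
  expect_equal(sum(s1$final_N) - 20, s1$novel)
})

test_that("stochastic means track the closed form at alpha = 1", {
  par <- selection_params(alpha = 1, k_d = 1)
  reps <- 12
  Ns <- t(sapply(1:reps, function(s)
    stochastic_growth(par, seed = s, N1 = 100, t_end = 1.5)$final_N))
  cf <- growth_closed_form(par, 100, 1.5, ncol(Ns))[1, ]
  m <- colMeans(Ns)
  se <- apply(Ns, 2, sd) / sqrt(reps)
  for (a in 2:6)
    expect_lt(abs(m[a] - cf[a]), 3 * se[a] + 1e-9)
})

test_that("lower selectivity yields fewer unique objects at matched events", {
  uniq <- function(alpha, seed) {
    s <- stochastic_growth(selection_params(alpha = alpha, k_d = 1), seed = seed,
                           N1 = 50, max_events = 300)
    sum(s$final_N) - s$final_N[1]
  }
  seeds <- 1:12
  u1 <- sapply(seeds, function(s) uniq(1, s))
  u05 <- sapply(seeds, function(s) uniq(0.5, s))
  u02 <- sapply(seeds, function(s) uniq(0.2, s))
  expect_lt(mean(u05), mean(u1))
  expect_lt(mean(u02), mean(u05))  # monotone in alpha on average
})

test_that("production off means all singletons and zero assembly", {
  for (s in 1:3) {
    d <- discovery_production_sim(selection_params(0.6, 1, 0), seed = s,
                                  t_end = 10, N1 = 50, M = 100)
    expect_true(all(d$objects$copies == 1))
    expect_identical(d$A_final, 0)
    expect_true(all(d$trajectory$A == 0))
  }
})

test_that("the mass budget ends the simulation cleanly", {
  d <- discovery_production_sim(selection_params(0.6, 5, 5), seed = 2,
                                t_end = 1000, N1 = 50, M = 40)
  expect_lte(d$mass_used, 40)
  expect_lte(d$t_final, 1000)
  expect_equal(sum(d$objects$copies), d$mass_used)
})

test_that("timescale regimes classify as documented", {
  expect_equal(regime_classify(0.001, 1), 1L)
  expect_equal(regime_classify(1000, 1), 2L)
  expect_equal(regime_classify(1, 1), 3L)
  expect_equal(regime_classify(5, 1, r_high = 4), 2L)  # configurable thresholds
  expect_error(regime_classify(-1, 1), "positive")
  expect_error(regime_classify(1, Inf), "positive")
})

test_that("the selection-parameter estimator is an explicit stub", {
  expect_error(estimate_selection_params(data.frame(t = 1, a = 1, N = 2)),
               "not implemented")
  expect_error(estimate_selection_params(data.frame(x = 1)), "t")
})
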