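small_data <- function(seed = 1, n = 50) {
  generate_dataset(mediation_condition(n = n, a = 0.39, b = 0.39,
                                       cprime = 0.39), seed = seed)
}

test_that("chains are bitwise reproducible given the seed", {
  d <- small_data()
  p1 <- gibbs_mediation(d, n_iter = 400, burn_in = 100, seed = 5)
  p2 <- gibbs_mediation(d, n_iter = 400, burn_in = 100, seed = 5)
  expect_identical(p1$paths, p2$paths)
  expect_identical(p1$variances, p2$variances)
})

test_that("variance draws stay positive and chains contain no NaNs", {
  d <- small_data(seed = 2)
  post <- gibbs_mediation(d, n_iter = 2000, burn_in = 200, seed = 6)
  expect_true(all(post$variances > 0))
  expect_false(anyNA(post$paths))
  expect_false(anyNA(post$variances))
})

test_that("an overwhelming prior pins the coefficients at its mean", {
  d <- small_data(seed = 3)
  post <- gibbs_mediation(d, priors = prior_spec(coef_precision = 1e10),
                          n_iter = 600, burn_in = 100, seed = 7)
  expect_lt(max(abs(colMeans(post$paths))), 1e-3)
})

test_that("diffuse posterior means agree with OLS within MC error at n=500", {
  # 20 seeds x 3 coefficients = 60 simultaneous checks; deviations are
  # standardized by batch-means MC standard errors and tested jointly (a
  # per-check 3-sigma bound would be expected to fail by chance alone)
  z <- numeric(0)
  for (s in 1:20) {
    d <- generate_dataset(mediation_condition(n = 500, a = 0.39, b = 0.39,
                                              cprime = 0.39), seed = 100 + s)
    fit <- fit_mediation(d)
    post <- gibbs_mediation(d, n_iter = 1500, burn_in = 300, seed = 200 + s)
    for (nm in c("a", "b", "cprime")) {
      mcse <- batch_mcse(post$paths[, nm])
      z <- c(z, (mean(post$paths[, nm]) - fit[[nm]]) / mcse)
    }
  }
  expect_lt(max(abs(z)), 4)          # no check beyond gross MC error
  expect_lt(abs(mean(z)), 1)         # no systematic posterior-OLS offset
  expect_lt(mean(abs(z) > 3), 0.1)   # 3-sigma exceedances stay exceptional
})

test_that("two-mediator chains recover all five paths", {
  d <- generate_dataset(mediation_condition(n = 1000, a1 = 0.314, b1 = 0.314,
                                            a2 = 0.101, b2 = 0.101,
                                            cprime = 0.4), seed = 9)
  fit <- fit_mediation(d)
  post <- gibbs_mediation(d, n_iter = 1200, burn_in = 200, seed = 10)
  for (nm in c("a1", "b1", "a2", "b2", "cprime"))
    expect_lt(abs(mean(post$paths[, nm]) - fit[[nm]]), 0.02)
  expect_true(all(post$rhat < 1.05, na.rm = TRUE))
})

test_that("effect-size draws apply the formulas with fixed standardizers", {
  d <- small_data(seed = 4)
  post <- gibbs_mediation(d, n_iter = 500, burn_in = 100, seed = 11)
  es <- effect_size_draws(post)
  ind <- post$paths[, "a"] * post$paths[, "b"]
  expect_equal(es[, "indirect"], ind)
  expect_equal(es[, "ab_ps"], ind / post$s_y)
  expect_equal(es[, "ab_fs"], ind * post$s_x / post$s_y)
  # zeroed path draws give zero standardized draws
  post0 <- post
  post0$paths[, c("a", "b")] <- 0
  expect_true(all(effect_size_draws(post0)[, "ab_ps"] == 0))
  expect_error(effect_size_draws(post, s_y = 0), "positive")
})

test_that("posterior median of ab_ps recovers the population value", {
  cond <- mediation_condition(n = 10000, a = 0.39, b = 0.39, cprime = 0.39)
  d <- generate_dataset(cond, seed = 15)
  post <- gibbs_mediation(d, n_iter = 1500, burn_in = 300, seed = 16)
  med <- posterior_point(effect_size_draws(post)[, "ab_ps"], "median")
  expect_lt(abs(med - true_effect_sizes(cond)$ab_ps), 0.02)
})

test_that("ratio draws change sign when c' straddles zero yet summarize", {
  d <- generate_dataset(mediation_condition(n = 50, a = 0.39, b = 0.39,
                                            cprime = 0), seed = 18)
  post <- gibbs_mediation(d, n_iter = 1000, burn_in = 200, seed = 19)
  r <- effect_size_draws(post)[, "ratio"]
  expect_true(any(r > 0, na.rm = TRUE) && any(r < 0, na.rm = TRUE))
  expect_true(is.finite(posterior_point(r, "median")))
})

test_that("posterior point summaries follow their definitions", {
  expect_equal(posterior_point(c(1, 2, 3), "mean"), 2)
  expect_equal(posterior_point(c(1, 2, 3), "median"), 2)
  expect_equal(posterior_point(c(0, 0, 0, 10), "mean"), 2.5)
  expect_equal(posterior_point(c(0, 0, 0, 10), "median"), 0)
  expect_true(is.na(posterior_point(rep(NA_real_, 5), "mean")))
})

test_that("equal-tail interval uses the same order-statistic rule", {
  draws <- as.numeric(1:1000)
  et <- equal_tail_interval(draws, 0.95)
  expect_equal(c(et$lower, et$upper), c(25, 975))
  et50 <- equal_tail_interval(draws, 0.5)
  expect_equal(c(et50$lower, et50$upper), c(250, 750))
  etc <- equal_tail_interval(rep(1.5, 100), 0.95)
  expect_equal(c(etc$lower, etc$upper), c(1.5, 1.5))
})

test_that("hpd interval matches the exhaustive-window oracle", {
  # hand case: right-skewed 5-point set
  got <- hpd_interval(c(0, 0.1, 0.2, 0.3, 5), 0.8)
  expect_equal(c(got$lower, got$upper), c(0, 0.3))
  # exhaustive oracle on random <=10-point sets
  set.seed(23)
  for (i in 1:50) {
    nd <- sample(3:10, 1)
    v <- round(rexp(nd), 2)
    lev <- sample(c(0.5, 0.8, 0.9), 1)
    got <- hpd_interval(v, lev)
    want <- reference_hpd(v, lev)
    expect_equal(c(got$lower, got$upper), want)
  }
  # constant draws
  hc <- hpd_interval(rep(2.5, 50), 0.9)
  expect_equal(c(hc$lower, hc$upper), c(2.5, 2.5))
})

test_that("hpd width never exceeds the equal-tail width", {
  set.seed(29)
  for (i in 1:30) {
    v <- switch(1 + i %% 3,
                rnorm(500),
                rgamma(500, shape = runif(1, 0.5, 3)),
                rbeta(500, 0.5, 2))
    for (lev in c(0.8, 0.95)) {
      hpd <- hpd_interval(v, lev)
      et <- equal_tail_interval(v, lev)
      expect_lte(hpd$upper - hpd$lower, et$upper - et$lower + 1e-12)
    }
  }
})

test_that("summarize_posterior reports all four effect sizes", {
  d <- small_data(seed = 30)
  post <- gibbs_mediation(d, n_iter = 600, burn_in = 100, seed = 31)
  tab <- summarize_posterior(post, level = 0.9)
  expect_equal(tab$estimator, c("ab_ps", "ab_fs", "proportion", "ratio"))
  expect_true(all(tab$hpd_upper - tab$hpd_lower <=
                    tab$et_upper - tab$et_lower + 1e-12))
})
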