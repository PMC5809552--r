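make_data <- function(seed = 3, n = 100) {
  cond <- mediation_condition(n = n, a = 0.39, b = 0.39, cprime = 0.39)
  generate_dataset(cond, seed = seed)
}

test_that("resampling is deterministic given the seed", {
  d <- make_data()
  d1 <- resample_estimates(d, "ab_ps", B = 200, seed = 10)
  d2 <- resample_estimates(d, "ab_ps", B = 200, seed = 10)
  expect_identical(d1$values, d2$values)
  expect_equal(d1$B, 200L)
  expect_equal(d1$observed, effect_sizes(fit_mediation(d))$ab_ps,
               tolerance = 1e-12)
})

test_that("bootstrap draw means track the observed estimate across seeds", {
  d <- make_data(seed = 17)
  obs <- effect_sizes(fit_mediation(d))$ab_ps
  devs <- vapply(1:10, function(s) {
    mean(resample_estimates(d, "ab_ps", B = 2000, seed = s)$values) - obs
  }, 0)
  expect_lt(abs(mean(devs)), 0.02)
  expect_lt(max(abs(devs)), 0.05)
})

test_that("rank-deficient resamples are redrawn and counted", {
  # binary X with a single treated unit: ~35% of resamples drop it
  set.seed(44)
  x <- c(1, rep(0, 9))
  m <- 0.5 * x + rnorm(10)
  y <- 0.3 * m + rnorm(10)
  d <- mediation_data(x = x, m = m, y = y, x_type = "binary")
  dr <- resample_estimates(d, "ab_ps", B = 200, seed = 2)
  expect_gt(dr$n_redrawn, 0)
  expect_false(anyNA(dr$values))
})

test_that("percentile interval follows the ceiling order-statistic rule", {
  draws <- as.numeric(1:1000)
  i95 <- percentile_interval(draws, 0.95)
  expect_equal(c(i95$lower, i95$upper), c(25, 975))
  i50 <- percentile_interval(draws, 0.5)
  expect_equal(c(i50$lower, i50$upper), c(250, 750))
  # degenerate draws give a degenerate interval
  ic <- percentile_interval(rep(3.2, 500), 0.95)
  expect_equal(c(ic$lower, ic$upper), c(3.2, 3.2))
  # too few defined draws -> undefined interval signal
  v <- c(1:50, rep(NA_real_, 950))
  expect_false(percentile_interval(v, 0.95)$defined)
})

test_that("percentile interval is equivariant under increasing transforms", {
  set.seed(12)
  draws <- rgamma(400, 2, 1)
  for (f in list(function(z) z^3, function(z) exp(z), function(z) 5 * z - 2)) {
    base <- percentile_interval(draws, 0.9)
    tran <- percentile_interval(f(draws), 0.9)
    expect_equal(c(tran$lower, tran$upper), f(c(base$lower, base$upper)),
                 tolerance = 1e-12)
  }
  # endpoints are realized draws
  expect_true(all(c(percentile_interval(draws, 0.9)$lower,
                    percentile_interval(draws, 0.9)$upper) %in% draws))
})

test_that("bias-corrected interval reduces to percentile at zero correction", {
  set.seed(9)
  draws <- rnorm(999)
  obs <- median(draws)   # odd count: p_below = (499 + 0.5)/999 ~ 0.5
  bc <- bias_corrected_interval(draws, 0.95, observed = obs)
  pc <- percentile_interval(draws, 0.95)
  expect_equal(c(bc$lower, bc$upper), c(pc$lower, pc$upper))
})

test_that("bias-corrected limits match direct normal-quantile arithmetic", {
  draws <- c(0.11, 0.23, 0.31, 0.34, 0.40, 0.47, 0.52, 0.60, 0.71, 0.95)
  obs <- 0.30   # below the median: negative z0 shifts both limits down
  for (lev in c(0.8, 0.95)) {
    got <- bias_corrected_interval(draws, lev, observed = obs)
    want <- reference_bc(draws, obs, lev)
    expect_equal(c(got$lower, got$upper), want)
  }
  # draws containing undefined entries are excluded from the order stats
  set.seed(77)
  v <- rnorm(500)
  v_na <- c(v, rep(NA_real_, 10))
  got <- bias_corrected_interval(v_na, 0.9, observed = 0)
  want <- reference_bc(v, 0, 0.9)
  expect_equal(c(got$lower, got$upper), want)
})

test_that("one-sided draw sets clamp z0 with a warning", {
  draws <- seq(1, 2, length.out = 300)
  expect_warning(bc <- bias_corrected_interval(draws, 0.95, observed = 0.5),
                 "clamped")
  expect_true(bc$defined)
  expect_equal(bc$lower, min(draws))  # interval collapses toward lower tail
  expect_warning(bias_corrected_interval(draws, 0.95, observed = 3),
                 "clamped")
})

test_that("bootstrap_ci wires estimate, draws and interval together", {
  d <- make_data(seed = 5, n = 60)
  res <- bootstrap_ci(d, "proportion", B = 300, level = 0.9,
                      method = "percentile", seed = 6)
  expect_s3_class(res$interval, "interval_estimate")
  expect_true(res$interval$lower <= res$estimate)
  expect_true(res$interval$upper >= res$estimate ||
                res$interval$upper >= res$interval$lower)
  expect_equal(res$draws$B, 300L)
})
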