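test_that("noiseless data are recovered exactly by OLS", {
  fit <- fit_single_mediator(noiseless_single())
  expect_equal(fit$a, 0.5, tolerance = 1e-12)
  expect_equal(fit$b, 0.3, tolerance = 1e-12)
  expect_equal(fit$cprime, 0.2, tolerance = 1e-12)
  expect_equal(fit$c, 0.2 + 0.5 * 0.3, tolerance = 1e-12)

  fit2 <- fit_two_mediator(noiseless_two())
  expect_equal(fit2$a1, 0.3, tolerance = 1e-12)
  expect_equal(fit2$b1, 0.3, tolerance = 1e-12)
  expect_equal(fit2$a2, 0.1, tolerance = 1e-12)
  expect_equal(fit2$b2, 0.1, tolerance = 1e-12)
  expect_equal(fit2$cprime, 0.4, tolerance = 1e-12)
})

test_that("4-point fit matches the normal equations solved directly", {
  x <- c(0, 1, 2, 4)
  m <- c(0.3, 1.1, 0.7, 2.5)
  y <- c(-0.2, 0.9, 1.4, 2.1)
  d <- mediation_data(x = x, m = m, y = y)
  fit <- fit_single_mediator(d)
  # independent oracle: solve X'X beta = X'y for each equation
  X1 <- cbind(1, x)
  X2 <- cbind(1, x, m)
  b1 <- solve(crossprod(X1), crossprod(X1, y))
  b2 <- solve(crossprod(X2), crossprod(X2, y))
  b3 <- solve(crossprod(X1), crossprod(X1, m))
  expect_equal(fit$c, unname(b1[2, 1]), tolerance = 1e-10)
  expect_equal(fit$cprime, unname(b2[2, 1]), tolerance = 1e-10)
  expect_equal(fit$b, unname(b2[3, 1]), tolerance = 1e-10)
  expect_equal(fit$a, unname(b3[2, 1]), tolerance = 1e-10)
  expect_equal(fit$s_x, sd(x))
  expect_equal(fit$s_y, sd(y))
})

test_that("moment-based estimates agree with lm() for both models", {
  set.seed(42)
  n <- 80
  x <- rnorm(n)
  m1 <- 0.3 * x + rnorm(n)
  m2 <- 0.6 * x + rnorm(n)
  y <- 0.2 * x + 0.4 * m1 - 0.1 * m2 + rnorm(n)
  d1 <- mediation_data(x = x, m = m1, y = y)
  f1 <- fit_single_mediator(d1)
  e1 <- medfx:::single_moment_estimates(cbind(x), cbind(m1), cbind(y))
  expect_equal(e1$a, f1$a, tolerance = 1e-12)
  expect_equal(e1$b, f1$b, tolerance = 1e-12)
  expect_equal(e1$cprime, f1$cprime, tolerance = 1e-12)
  expect_equal(e1$c, f1$c, tolerance = 1e-12)

  d2 <- mediation_data(x = x, m1 = m1, m2 = m2, y = y)
  f2 <- fit_two_mediator(d2)
  e2 <- medfx:::two_moment_estimates(cbind(x), cbind(m1), cbind(m2),
                                     cbind(y))
  expect_equal(e2$a1, f2$a1, tolerance = 1e-12)
  expect_equal(e2$b1, f2$b1, tolerance = 1e-12)
  expect_equal(e2$a2, f2$a2, tolerance = 1e-12)
  expect_equal(e2$b2, f2$b2, tolerance = 1e-12)
  expect_equal(e2$cprime, f2$cprime, tolerance = 1e-12)
})

test_that("large-sample slopes approach the population paths", {
  cond <- mediation_condition(n = 1e6, a = 0.39, b = 0.39, cprime = 0.39)
  fit <- fit_mediation(generate_dataset(cond, seed = 11))
  expect_lt(abs(fit$a - 0.39), 0.01)
  expect_lt(abs(fit$b - 0.39), 0.01)
  expect_lt(abs(fit$cprime - 0.39), 0.01)

  cond2 <- mediation_condition(n = 1e6, a1 = 0.314, b1 = 0.314, a2 = 0.314,
                               b2 = 0.314, cprime = 0.4)
  fit2 <- fit_mediation(generate_dataset(cond2, seed = 12))
  expect_lt(max(abs(c(fit2$a1, fit2$b1, fit2$a2, fit2$b2) - 0.314)), 0.01)
  expect_lt(abs(fit2$cprime - 0.4), 0.01)
})

test_that("rank-deficient designs are rejected", {
  set.seed(5)
  n <- 20
  x <- rnorm(n)
  m <- 0.4 * x + rnorm(n)
  y <- 0.2 * x + 0.3 * m + rnorm(n)
  d_const <- mediation_data(x = rep(1, n), m = m, y = y, x_type = "binary")
  expect_error(fit_single_mediator(d_const), "rank")
  d_dup <- mediation_data(x = x, m1 = m, m2 = m, y = y)
  expect_error(fit_two_mediator(d_dup), "rank")
})

test_that("OLS identity c = c' + sum(a*b) holds on random full-rank data", {
  set.seed(99)
  for (k in 1:20) {
    n <- sample(20:200, 1)
    x <- if (k %% 2 == 0) rnorm(n) else rbinom(n, 1, 0.5)
    if (length(unique(x)) < 2) x[1] <- 1 - x[1]
    m1 <- runif(1, -1, 1) * x + rnorm(n)
    if (k <= 10) {
      y <- runif(1, -1, 1) * x + runif(1, -1, 1) * m1 + rnorm(n)
      fit <- fit_single_mediator(
        mediation_data(x = x, m = m1, y = y,
                       x_type = if (k %% 2 == 0) "continuous" else "binary"))
      expect_lt(abs(fit$c - (fit$cprime + fit$a * fit$b)), 1e-10)
    } else {
      m2 <- runif(1, -1, 1) * x + rnorm(n)
      y <- runif(1, -1, 1) * x + runif(1, -1, 1) * m1 +
        runif(1, -1, 1) * m2 + rnorm(n)
      fit <- fit_two_mediator(
        mediation_data(x = x, m1 = m1, m2 = m2, y = y,
                       x_type = if (k %% 2 == 0) "continuous" else "binary"))
      expect_lt(abs(fit$c - (fit$cprime + fit$a1 * fit$b1 +
                               fit$a2 * fit$b2)), 1e-10)
    }
  }
})

test_that("fitting is invariant to row order", {
  set.seed(7)
  n <- 50
  x <- rnorm(n); m <- 0.5 * x + rnorm(n); y <- 0.2 * x + 0.3 * m + rnorm(n)
  fit1 <- fit_single_mediator(mediation_data(x = x, m = m, y = y))
  p <- sample(n)
  fit2 <- fit_single_mediator(mediation_data(x = x[p], m = m[p], y = y[p]))
  expect_equal(fit1$a, fit2$a)
  expect_equal(fit1$b, fit2$b)
  expect_equal(fit1$cprime, fit2$cprime)
  expect_equal(fit1$residual_variances, fit2$residual_variances)
})

test_that("population moments match the closed forms and trivial cases", {
  c0 <- mediation_condition(n = 100, a = 0, b = 0, cprime = 0)
  p0 <- population_moments(c0)
  expect_equal(p0$s_y, 1)
  expect_equal(p0$s_x, 1)

  c1 <- mediation_condition(n = 100, a = 0.39, b = 0.39, cprime = 0.39)
  p1 <- population_moments(c1)
  expect_equal(p1$s_y^2, (0.39 * 0.39 + 0.39)^2 + 0.39^2 + 1)
  expect_equal(p1$s_y, sqrt(1.44597), tolerance = 1e-5)
  expect_equal(effect_sizes(p1)$ab_ps, 0.1521 / sqrt(1.44597),
               tolerance = 1e-5)

  cb <- mediation_condition(n = 100, a = 0.39, b = 0.39, cprime = 0.39,
                            x_type = "binary", binary_p = 0.5)
  pb <- population_moments(cb)
  expect_equal(pb$s_y^2, 0.25 * 0.5421^2 + 0.1521 + 1, tolerance = 1e-10)
  expect_equal(pb$s_x, 0.5)

  c2 <- mediation_condition(n = 100, a1 = 0.314, b1 = 0.314, a2 = 0.577,
                            b2 = 0.577, cprime = 0.4)
  p2 <- population_moments(c2)
  ind <- 0.314^2 + 0.577^2
  expect_equal(p2$s_y^2, (ind + 0.4)^2 + 0.314^2 + 0.577^2 + 1)
  expect_equal(p2$c, p2$cprime + ind)
})

test_that("generated data reproduce the model-implied variance of Y", {
  cond <- mediation_condition(n = 1e6, a = 0.39, b = 0.39, cprime = 0.39)
  d <- generate_dataset(cond, seed = 21)
  expect_lt(abs(var(d$y) / 1.44597 - 1), 0.01)
  # null structure: all correlations near zero
  cond0 <- mediation_condition(n = 1e4, a = 0, b = 0, cprime = 0)
  d0 <- generate_dataset(cond0, seed = 22)
  cors <- cor(cbind(d0$x, d0$mediators[[1]], d0$y))
  expect_lt(max(abs(cors[upper.tri(cors)])), 4 / sqrt(1e4))
})

test_that("generate_dataset is deterministic and validates inputs", {
  cond <- mediation_condition(n = 30, a = 0.14, b = 0.14, cprime = 0,
                              x_type = "binary")
  d1 <- generate_dataset(cond, seed = 3)
  d2 <- generate_dataset(cond, seed = 3)
  expect_identical(d1, d2)
  expect_true(all(d1$x %in% c(0, 1)))
  expect_error(mediation_condition(n = 5, a = 0.1, b = 0.1), "n >= 10")
  expect_error(mediation_data(x = 1:3, m = 1:3, y = 1:3), "at least 4")
})

test_that("datasets and fitted coefficients round-trip through CSV", {
  set.seed(13)
  n <- 40
  x <- rnorm(n); m <- 0.5 * x + rnorm(n); y <- 0.2 * x + 0.3 * m + rnorm(n)
  path <- tempfile(fileext = ".csv")
  write.csv(data.frame(x = x, m = m, y = y), path, row.names = FALSE)
  d <- read_mediation_data(path)
  expect_equal(d$x, x, tolerance = 1e-12)
  expect_equal(d$mediators[[1]], m, tolerance = 1e-12)

  fit <- fit_single_mediator(d)
  cpath <- tempfile(fileext = ".csv")
  write_path_estimates(fit, cpath)
  coefs <- read.csv(cpath)
  expect_equal(coefs$value[coefs$term == "a"], fit$a)
  expect_equal(coefs$value[coefs$term == "s_y"], fit$s_y)
  unlink(c(path, cpath))
})
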