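#' Diffuse prior specification for the mediation regressions
#'
#' Regression coefficients (including intercepts) get independent normal
#' priors with mean `coef_mean` and precision `coef_precision`; residual
#' variances get inverse-gamma priors with shape `var_shape` and rate
#' (inverse scale) `var_inverse_scale`. The defaults are the conventional
#' diffuse choice: N(0, precision 1e-3) and IG(0.01, 0.01).
#'
#' @param coef_mean Prior mean for every coefficient.
#' @param coef_precision Prior precision (1/variance) for every coefficient;
#'   must be positive.
#' @param var_shape,var_inverse_scale Inverse-gamma hyperparameters for the
#'   residual variances; must be positive.
#' @return An object of class `prior_spec`.
#' @export
prior_spec <- function(coef_mean = 0, coef_precision = 1e-3,
                       var_shape = 0.01, var_inverse_scale = 0.01) {
  stopifnot(is.finite(coef_mean), coef_precision > 0,
            var_shape > 0, var_inverse_scale > 0)
  structure(list(coef_mean = coef_mean, coef_precision = coef_precision,
                 var_shape = var_shape,
                 var_inverse_scale = var_inverse_scale),
            class = "prior_spec")
}

# Conjugate Gibbs chain for one normal linear regression y ~ Xmat (with
# intercept column). Blocks: full coefficient vector | variance (exact
# multivariate-normal conditional), then variance | coefficients.
gibbs_equation <- function(Xmat, y, prior, n_iter, burn_in) {
  n <- nrow(Xmat); p <- ncol(Xmat)
  XtX <- crossprod(Xmat)
  Xty <- drop(crossprod(Xmat, y))
  yty <- sum(y * y)
  tau0 <- prior$coef_precision
  mu0 <- rep(prior$coef_mean, p)
  shape_n <- prior$var_shape + n / 2
  ols <- tryCatch(solve(XtX, Xty), error = function(e)
    stop("rank-deficient design in Gibbs sampler"))
  beta <- ols
  sigma2 <- max(mean((y - drop(Xmat %*% beta))^2), 1e-8)
  keep <- n_iter - burn_in
  beta_out <- matrix(NA_real_, keep, p)
  sig_out <- numeric(keep)
  Ip <- diag(tau0, p)
  for (it in seq_len(n_iter)) {
    prec <- XtX / sigma2 + Ip
    U <- chol(prec)
    bhat <- backsolve(U, forwardsolve(t(U), Xty / sigma2 + tau0 * mu0))
    beta <- bhat + backsolve(U, stats::rnorm(p))
    rss <- yty - 2 * sum(beta * Xty) + drop(crossprod(beta, XtX %*% beta))
    rss <- max(rss, 0)
    sigma2 <- 1 / stats::rgamma(1, shape_n,
                                rate = prior$var_inverse_scale + rss / 2)
    if (!is.finite(sigma2) || sigma2 <= 0 || !all(is.finite(beta)))
      stop(sprintf("non-finite Gibbs draw at iteration %d", it))
    if (it > burn_in) {
      beta_out[it - burn_in, ] <- beta
      sig_out[it - burn_in] <- sigma2
    }
  }
  list(beta = beta_out, sigma2 = sig_out)
}

# Split-chain potential scale reduction on one vector of retained draws.
split_rhat <- function(v) {
  m <- floor(length(v) / 2)
  if (m < 2) return(NA_real_)
  halves <- cbind(v[seq_len(m)], v[seq_len(m) + m])
  W <- mean(apply(halves, 2, stats::var))
  B <- m * stats::var(colMeans(halves))
  if (W <= 0) return(NA_real_)
  sqrt(((m - 1) / m * W + B / m) / W)
}

#' Gibbs sampling of the mediation regressions
#'
#' Samples the posterior of the mediator equation(s) and the outcome
#' equation (each including an intercept) by conjugate Gibbs updates:
#' coefficients given variance from the exact multivariate-normal
#' conditional, variance given coefficients from the inverse gamma with
#' shape `var_shape + n/2` and rate `var_inverse_scale + RSS/2`. The
#' equations have a priori independent parameters and factoring likelihoods,
#' so their chains are run independently (in a fixed order, sharing one
#' seeded RNG stream — bitwise reproducible given `seed`).
#'
#' @param data A [mediation_data()] object.
#' @param priors A [prior_spec()].
#' @param n_iter Total iterations per equation (default 11000).
#' @param burn_in Burn-in iterations discarded from the front (default 1000).
#' @param seed Integer seed.
#' @return An object of class `posterior_draws`: list with `paths` (matrix
#'   of retained draws of `a`, `b`, `cprime` — or `a1`, `b1`, `a2`, `b2`,
#'   `cprime`), `variances` (matrix of residual-variance draws per
#'   equation), `s_x`, `s_y` (sample SDs of the data), `rhat` (split-chain
#'   potential scale reduction per path), `n_iter`, `burn_in`, `seed`.
#' @examples
#' cond <- mediation_condition(n = 50, a = 0.39, b = 0.39, cprime = 0.39)
#' post <- gibbs_mediation(generate_dataset(cond, 1), n_iter = 600,
#'                         burn_in = 100, seed = 2)
#' posterior_point(effect_size_draws(post)[, "ab_ps"], "median")
#' @export
gibbs_mediation <- function(data, priors = prior_spec(), n_iter = 11000L,
                            burn_in = 1000L, seed = NULL) {
  stopifnot(inherits(data, "mediation_data"), inherits(priors, "prior_spec"))
  n_iter <- as.integer(n_iter); burn_in <- as.integer(burn_in)
  if (n_iter <= burn_in) stop("n_iter must exceed burn_in")
  if (!is.null(seed)) set.seed(as.integer(seed))
  one <- rep(1, data$n)
  if (data$n_mediators == 1L) {
    m <- data$mediators[[1]]
    eq_m <- gibbs_equation(cbind(one, data$x), m, priors, n_iter, burn_in)
    eq_y <- gibbs_equation(cbind(one, data$x, m), data$y, priors, n_iter,
                           burn_in)
    paths <- cbind(a = eq_m$beta[, 2], b = eq_y$beta[, 3],
                   cprime = eq_y$beta[, 2])
    variances <- cbind(var_m = eq_m$sigma2, var_y = eq_y$sigma2)
  } else {
    m1 <- data$mediators[[1]]; m2 <- data$mediators[[2]]
    eq_m1 <- gibbs_equation(cbind(one, data$x), m1, priors, n_iter, burn_in)
    eq_m2 <- gibbs_equation(cbind(one, data$x), m2, priors, n_iter, burn_in)
    eq_y <- gibbs_equation(cbind(one, data$x, m1, m2), data$y, priors,
                           n_iter, burn_in)
    paths <- cbind(a1 = eq_m1$beta[, 2], b1 = eq_y$beta[, 3],
                   a2 = eq_m2$beta[, 2], b2 = eq_y$beta[, 4],
                   cprime = eq_y$beta[, 2])
    variances <- cbind(var_m1 = eq_m1$sigma2, var_m2 = eq_m2$sigma2,
                       var_y = eq_y$sigma2)
  }
  structure(list(paths = paths, variances = variances,
                 s_x = stats::sd(data$x), s_y = stats::sd(data$y),
                 n_mediators = data$n_mediators,
                 rhat = apply(paths, 2, split_rhat),
                 n_iter = n_iter, burn_in = burn_in, seed = seed),
            class = "posterior_draws")
}

#' @export
print.posterior_draws <- function(x, ...) {
  cat(sprintf("<posterior_draws> %d retained draws (%d iter, %d burn-in)\n",
              nrow(x$paths), x$n_iter, x$burn_in))
  cat("  split-chain PSRF:",
      paste(names(x$rhat), round(x$rhat, 3), sep = "=", collapse = ", "),
      "\n")
  invisible(x)
}

#' Per-iteration effect-size draws from a posterior
#'
#' Applies the four effect-size formulas to every retained draw of the path
#' coefficients, using fixed standardizers (by default the sample `s_x`,
#' `s_y` recorded at fit time, matching the frequentist estimator). Ratio
#' draws are `NA` at draws with `cprime` exactly zero; proportion draws are
#' `NA` at zero total effect.
#'
#' @param post A [gibbs_mediation()] result.
#' @param s_x,s_y Standardizers; default to the sample SDs stored in `post`.
#' @return Matrix with one row per retained draw and columns `indirect`,
#'   `ab_ps`, `ab_fs`, `proportion`, `ratio`.
#' @export
effect_size_draws <- function(post, s_x = post$s_x, s_y = post$s_y) {
  stopifnot(inherits(post, "posterior_draws"))
  if (!is.finite(s_x) || s_x <= 0 || !is.finite(s_y) || s_y <= 0)
    stop("standardizers must be positive")
  p <- post$paths
  ind <- if (post$n_mediators == 1L) p[, "a"] * p[, "b"] else
    p[, "a1"] * p[, "b1"] + p[, "a2"] * p[, "b2"]
  cp <- p[, "cprime"]
  total <- ind + cp
  cbind(indirect = ind,
        ab_ps = ind / s_y,
        ab_fs = ind * s_x / s_y,
        proportion = ifelse(total == 0, NA_real_, ind / total),
        ratio = ifelse(cp == 0, NA_real_, ind / cp))
}

#' Posterior point summary
#'
#' @param draws Numeric vector of posterior draws (`NA` = undefined).
#' @param which `"mean"` or `"median"`.
#' @return The arithmetic mean or sample median of the defined draws; `NA`
#'   if none are defined.
#' @export
posterior_point <- function(draws, which = c("mean", "median")) {
  which <- match.arg(which)
  v <- draws[!is.na(draws)]
  if (length(v) == 0L) return(NA_real_)
  if (which == "mean") mean(v) else stats::median(v)
}

#' Equal-tail credibility interval
#'
#' The `alpha/2` and `1 - alpha/2` posterior quantiles by the same
#' ceiling-rule order statistics as [percentile_interval()].
#'
#' @param draws Numeric vector of posterior draws.
#' @param level Nominal probability content.
#' @return An [interval_estimate()] with method `"equal_tail"`.
#' @export
equal_tail_interval <- function(draws, level = 0.95) {
  v <- draw_values(draws)
  defined <- v[!is.na(v)]
  if (length(defined) < ceiling(level * length(v)))
    return(interval_estimate(NA_real_, NA_real_, level, "equal_tail"))
  b <- order_stat_interval(sort(defined), level)
  interval_estimate(b[1], b[2], level, "equal_tail")
}

#' Highest posterior density interval
#'
#' Among all contiguous windows of `ceiling(level * n_defined)` sorted
#' draws, returns the narrowest (ties broken toward the lowest lower
#' bound). By construction its width never exceeds the equal-tail width on
#' the same draws.
#'
#' @param draws Numeric vector of posterior draws.
#' @param level Nominal probability content.
#' @return An [interval_estimate()] with method `"hpd"`.
#' @export
hpd_interval <- function(draws, level = 0.95) {
  v <- draw_values(draws)
  defined <- v[!is.na(v)]
  if (length(defined) < ceiling(level * length(v)))
    return(interval_estimate(NA_real_, NA_real_, level, "hpd"))
  sorted <- sort(defined)
  nd <- length(sorted)
  m <- min(max(ceil_idx(level * nd), 1L), nd)
  n_win <- nd - m + 1L
  widths <- sorted[m:nd] - sorted[seq_len(n_win)]
  i <- which.min(widths)  # which.min takes the first (lowest) minimizer
  interval_estimate(sorted[i], sorted[i + m - 1L], level, "hpd")
}

#' Posterior summary table for all four effect sizes
#'
#' @param post A [gibbs_mediation()] result.
#' @param level Credibility level for the intervals.
#' @return A data.frame with one row per effect size: posterior mean and
#'   median, equal-tail and HPD limits, and the number of undefined draws.
#' @export
summarize_posterior <- function(post, level = 0.95) {
  es <- effect_size_draws(post)
  rows <- lapply(ES_NAMES, function(nm) {
    v <- es[, nm]
    et <- equal_tail_interval(v, level)
    hpd <- hpd_interval(v, level)
    data.frame(estimator = nm,
               post_mean = posterior_point(v, "mean"),
               post_median = posterior_point(v, "median"),
               et_lower = et$lower, et_upper = et$upper,
               hpd_lower = hpd$lower, hpd_upper = hpd$upper,
               n_undefined = sum(is.na(v)))
  })
  do.call(rbind, rows)
}
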