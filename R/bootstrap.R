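#' Interval estimate container
#'
#' @param lower,upper Interval bounds (`NA` for an undefined interval).
#' @param level Nominal probability content, in (0, 1).
#' @param method One of `"percentile"`, `"bias_corrected"`, `"equal_tail"`,
#'   `"hpd"`.
#' @return An object of class `interval_estimate`.
#' @export
interval_estimate <- function(lower, upper, level,
                              method = c("percentile", "bias_corrected",
                                         "equal_tail", "hpd")) {
  method <- match.arg(method)
  if (!(level > 0 && level < 1)) stop("level must be in (0, 1)")
  if (!is.na(lower) && !is.na(upper) && lower > upper)
    stop("lower must not exceed upper")
  structure(list(lower = lower, upper = upper, level = level,
                 method = method, defined = !is.na(lower) && !is.na(upper)),
            class = "interval_estimate")
}

#' @export
print.interval_estimate <- function(x, digits = 4, ...) {
  cat(sprintf("<interval_estimate> %s %.0f%%: [%s, %s]\n", x$method,
              100 * x$level, signif(x$lower, digits), signif(x$upper, digits)))
  invisible(x)
}

# ---- resampling core ------------------------------------------------------

# B case resamples of one dataset, all five effect-size columns at once.
# Rank-deficient resamples (possible for binary X) are redrawn from the
# current RNG stream, up to `max_rounds` passes. Returns list(values = B x 5
# matrix, n_redrawn).
boot_effect_size_matrix <- function(data, B, max_rounds = 100L) {
  n <- data$n
  est_fun <- if (data$n_mediators == 1L) {
    function(idx) {
      dim(idx) <- c(n, length(idx) / n)
      single_moment_estimates(matrix(data$x[idx], n),
                              matrix(data$mediators[[1]][idx], n),
                              matrix(data$y[idx], n))
    }
  } else {
    function(idx) {
      dim(idx) <- c(n, length(idx) / n)
      two_moment_estimates(matrix(data$x[idx], n),
                           matrix(data$mediators[[1]][idx], n),
                           matrix(data$mediators[[2]][idx], n),
                           matrix(data$y[idx], n))
    }
  }
  idx <- sample.int(n, n * B, replace = TRUE)
  est <- est_fun(idx)
  values <- moment_effect_sizes(est, data$n_mediators)
  n_redrawn <- 0L
  bad <- which(!est$ok)
  rounds <- 0L
  while (length(bad) > 0L) {
    rounds <- rounds + 1L
    if (rounds > max_rounds)
      stop(sprintf(
        "bootstrap resampling failed: %d resample(s) still rank-deficient after %d redraw rounds",
        length(bad), max_rounds))
    n_redrawn <- n_redrawn + length(bad)
    idx2 <- sample.int(n, n * length(bad), replace = TRUE)
    est2 <- est_fun(idx2)
    values[bad, ] <- moment_effect_sizes(est2, data$n_mediators)
    bad <- bad[!est2$ok]
  }
  list(values = values, n_redrawn = n_redrawn)
}

observed_effect_sizes <- function(data) {
  if (data$n_mediators == 1L) {
    est <- single_moment_estimates(cbind(data$x), cbind(data$mediators[[1]]),
                                   cbind(data$y))
  } else {
    est <- two_moment_estimates(cbind(data$x), cbind(data$mediators[[1]]),
                                cbind(data$mediators[[2]]), cbind(data$y))
  }
  if (!est$ok) stop("rank-deficient design in the observed data")
  drop(moment_effect_sizes(est, data$n_mediators))
}

#' Bootstrap draws of an effect-size estimator
#'
#' Case resampling: draws `B` samples of size `n` with replacement from the
#' rows of `data`, refits the mediation regressions on each, and evaluates
#' the chosen effect-size functional. Resamples with rank-deficient designs
#' (e.g. a constant X in a binary-X resample) are redrawn and counted.
#' Deterministic given `seed`.
#'
#' @param data A [mediation_data()] object.
#' @param estimator One of `"ab_ps"`, `"ab_fs"`, `"proportion"`, `"ratio"`,
#'   `"indirect"`.
#' @param B Number of bootstrap resamples (>= 100).
#' @param seed Integer seed.
#' @return An object of class `bootstrap_draws`: list with `values`
#'   (length-`B` numeric, `NA` marking undefined estimates), `observed`
#'   (full-sample estimate), `B`, `n_undefined`, `n_redrawn` and
#'   `estimator`.
#' @examples
#' cond <- mediation_condition(n = 100, a = 0.39, b = 0.39, cprime = 0.39)
#' d <- generate_dataset(cond, seed = 3)
#' dr <- resample_estimates(d, "ab_ps", B = 200, seed = 4)
#' percentile_interval(dr, 0.95)
#' @export
resample_estimates <- function(data, estimator = c("ab_ps", "ab_fs",
                                                   "proportion", "ratio",
                                                   "indirect"),
                               B = 1000L, seed = NULL) {
  stopifnot(inherits(data, "mediation_data"))
  estimator <- match.arg(estimator)
  if (B < 100) stop("B must be at least 100")
  if (!is.null(seed)) set.seed(as.integer(seed))
  bm <- boot_effect_size_matrix(data, as.integer(B))
  values <- bm$values[, estimator]
  obs <- observed_effect_sizes(data)[[estimator]]
  structure(list(values = values, observed = obs, B = as.integer(B),
                 n_undefined = sum(is.na(values)),
                 n_redrawn = bm$n_redrawn, estimator = estimator),
            class = "bootstrap_draws")
}

#' @export
print.bootstrap_draws <- function(x, ...) {
  cat(sprintf("<bootstrap_draws> %s: B = %d, observed = %.4g, %d undefined\n",
              x$estimator, x$B, x$observed, x$n_undefined))
  invisible(x)
}

# ---- interval rules -------------------------------------------------------

# ceiling with a fuzz so that e.g. 0.025 * 1000 lands on 25, not 26
ceil_idx <- function(x) as.integer(ceiling(x - 1e-9))

# k-th order statistics by the ceiling rule (endpoints are realized draws).
order_stat_interval <- function(sorted, level) {
  nd <- length(sorted)
  alpha <- 1 - level
  k_lo <- min(max(ceil_idx(alpha / 2 * nd), 1L), nd)
  k_hi <- min(max(ceil_idx((1 - alpha / 2) * nd), 1L), nd)
  c(sorted[k_lo], sorted[k_hi])
}

draw_values <- function(draws) {
  if (inherits(draws, "bootstrap_draws")) draws$values
  else as.numeric(draws)
}

#' Percentile bootstrap confidence interval
#'
#' Bounds are the `ceiling((alpha/2) * B)`-th and
#' `ceiling((1 - alpha/2) * B)`-th order statistics of the defined draws
#' (`alpha = 1 - level`); no interpolation, so the endpoints are realized
#' bootstrap estimates. Requires at least `ceiling(level * B)` defined
#' draws, otherwise the interval is returned undefined (`NA` bounds).
#'
#' @param draws A [resample_estimates()] result (or a bare numeric vector of
#'   draws).
#' @param level Nominal coverage, default 0.95.
#' @return An [interval_estimate()] with method `"percentile"`.
#' @export
percentile_interval <- function(draws, level = 0.95) {
  v <- draw_values(draws)
  defined <- v[!is.na(v)]
  if (length(defined) < ceiling(level * length(v)))
    return(interval_estimate(NA_real_, NA_real_, level, "percentile"))
  b <- order_stat_interval(sort(defined), level)
  interval_estimate(b[1], b[2], level, "percentile")
}

#' Bias-corrected bootstrap confidence interval
#'
#' Computes `z0 = qnorm(p_below)` where `p_below` is the fraction of defined
#' draws below the observed estimate (ties counted half), then takes the
#' order statistics at the adjusted proportions
#' `pnorm(2 * z0 + qnorm(alpha/2))` and `pnorm(2 * z0 + qnorm(1 - alpha/2))`.
#' Reduces exactly to [percentile_interval()] when the observed estimate is
#' the median of the draws. When all draws fall on one side of the observed
#' value, `z0` is clamped to `qnorm(1/(B+1))` or `qnorm(B/(B+1))` with a
#' warning.
#'
#' @param draws A [resample_estimates()] result, or a numeric vector of
#'   draws together with `observed`.
#' @param level Nominal coverage, default 0.95.
#' @param observed Full-sample estimate; taken from `draws` when it is a
#'   `bootstrap_draws` object.
#' @return An [interval_estimate()] with method `"bias_corrected"`.
#' @export
bias_corrected_interval <- function(draws, level = 0.95, observed = NULL) {
  if (inherits(draws, "bootstrap_draws") && is.null(observed))
    observed <- draws$observed
  v <- draw_values(draws)
  if (is.null(observed) || !is.finite(observed))
    stop("a finite observed estimate is required")
  defined <- v[!is.na(v)]
  nd <- length(defined)
  if (nd < ceiling(level * length(v)))
    return(interval_estimate(NA_real_, NA_real_, level, "bias_corrected"))
  p_below <- (sum(defined < observed) + 0.5 * sum(defined == observed)) / nd
  if (p_below <= 0) {
    warning("all bootstrap draws at or above the observed estimate; z0 clamped")
    z0 <- stats::qnorm(1 / (nd + 1))
  } else if (p_below >= 1) {
    warning("all bootstrap draws at or below the observed estimate; z0 clamped")
    z0 <- stats::qnorm(nd / (nd + 1))
  } else {
    z0 <- stats::qnorm(p_below)
  }
  alpha <- 1 - level
  sorted <- sort(defined)
  p_lo <- stats::pnorm(2 * z0 + stats::qnorm(alpha / 2))
  p_hi <- stats::pnorm(2 * z0 + stats::qnorm(1 - alpha / 2))
  k_lo <- min(max(ceil_idx(p_lo * nd), 1L), nd)
  k_hi <- min(max(ceil_idx(p_hi * nd), 1L), nd)
  interval_estimate(sorted[k_lo], sorted[k_hi], level, "bias_corrected")
}

#' Bootstrap confidence interval for a mediation effect size
#'
#' Convenience wrapper: resamples, then applies the requested interval rule.
#'
#' @inheritParams resample_estimates
#' @param level Nominal coverage.
#' @param method `"percentile"` or `"bias_corrected"`.
#' @return A list with `estimate` (full-sample value), `interval` (an
#'   [interval_estimate()]) and `draws` (the [resample_estimates()] result).
#' @export
bootstrap_ci <- function(data, estimator = c("ab_ps", "ab_fs", "proportion",
                                             "ratio", "indirect"),
                         B = 1000L, level = 0.95,
                         method = c("percentile", "bias_corrected"),
                         seed = NULL) {
  estimator <- match.arg(estimator)
  method <- match.arg(method)
  dr <- resample_estimates(data, estimator, B = B, seed = seed)
  int <- if (method == "percentile") percentile_interval(dr, level)
  else bias_corrected_interval(dr, level)
  list(estimate = dr$observed, interval = int, draws = dr)
}
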