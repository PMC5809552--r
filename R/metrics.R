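#' Point-estimate recovery metrics over replications
#'
#' @param estimates Numeric vector of per-replication estimates (`NA` =
#'   undefined, excluded and counted).
#' @param truth True (population) value of the estimand.
#' @return A list: `bias` (mean estimate minus truth), `relative_bias`
#'   (bias/truth, `NA` when truth is 0 or undefined), `sd` (sample SD of
#'   the defined estimates, the efficiency measure), `standardized_bias`
#'   (bias/sd, `NA` at zero sd), `reps_used`, `reps_undefined`.
#' @export
point_metrics <- function(estimates, truth) {
  v <- estimates[!is.na(estimates)]
  n_und <- length(estimates) - length(v)
  if (length(v) < 2L)
    return(list(bias = NA_real_, relative_bias = NA_real_, sd = NA_real_,
                standardized_bias = NA_real_, reps_used = length(v),
                reps_undefined = n_und))
  if (is.na(truth))
    return(list(bias = NA_real_, relative_bias = NA_real_,
                sd = stats::sd(v), standardized_bias = NA_real_,
                reps_used = length(v), reps_undefined = n_und))
  bias <- mean(v) - truth
  s <- stats::sd(v)
  list(bias = bias,
       relative_bias = if (truth == 0) NA_real_ else bias / truth,
       sd = s,
       standardized_bias = if (s == 0) NA_real_ else bias / s,
       reps_used = length(v), reps_undefined = n_und)
}

#' Interval-estimator metrics over replications
#'
#' Power and Type I error use the same predicate — the interval excludes
#' zero — and the label depends only on the true effect size: `type1` when
#' the truth is zero, `power` otherwise. Coverage is the proportion of
#' defined intervals containing the truth (`NA` when the truth is
#' undefined). Imbalance is the disparity between right-side and left-side
#' misses: `P(truth > upper) - P(truth < lower)`.
#'
#' @param lower,upper Numeric vectors of per-replication interval bounds
#'   (`NA` = undefined interval, excluded and counted).
#' @param truth True effect-size value, or `NA` if undefined.
#' @return A list: `rate` (power or Type I error), `rate_type` (`"power"`,
#'   `"type1"` or `NA` when the truth is undefined), `coverage`,
#'   `width_mean`, `imbalance`, `reps_used`, `reps_undefined`.
#' @export
interval_metrics <- function(lower, upper, truth) {
  stopifnot(length(lower) == length(upper))
  def <- !is.na(lower) & !is.na(upper)
  lo <- lower[def]; up <- upper[def]
  n_und <- sum(!def)
  if (length(lo) == 0L)
    return(list(rate = NA_real_, rate_type = NA_character_,
                coverage = NA_real_, width_mean = NA_real_,
                imbalance = NA_real_, reps_used = 0L,
                reps_undefined = n_und))
  excl0 <- mean(lo > 0 | up < 0)
  if (is.na(truth)) {
    list(rate = excl0, rate_type = NA_character_, coverage = NA_real_,
         width_mean = mean(up - lo), imbalance = NA_real_,
         reps_used = length(lo), reps_undefined = n_und)
  } else {
    list(rate = excl0,
         rate_type = if (truth == 0) "type1" else "power",
         coverage = mean(lo <= truth & truth <= up),
         width_mean = mean(up - lo),
         imbalance = mean(truth > up) - mean(truth < lo),
         reps_used = length(lo), reps_undefined = n_und)
  }
}

#' Bradley robustness classification
#'
#' Classifies an empirical rate against Bradley's liberal robustness bands:
#' Type I error acceptable in \[0.025, 0.075\], coverage acceptable in
#' \[0.925, 0.975\] (inclusive).
#'
#' @param rate A proportion in \[0, 1\].
#' @param kind `"type1"` or `"coverage"`.
#' @return `"below"`, `"within"` or `"above"` (or `NA` for `NA` input).
#' @export
bradley_assess <- function(rate, kind = c("type1", "coverage")) {
  kind <- match.arg(kind)
  if (is.na(rate)) return(NA_character_)
  stopifnot(rate >= 0, rate <= 1)
  band <- if (kind == "type1") c(0.025, 0.075) else c(0.925, 0.975)
  if (rate < band[1]) "below" else if (rate > band[2]) "above" else "within"
}
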