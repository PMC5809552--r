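#' Population path coefficients and model-implied moments
#'
#' Closed-form population ("true") counterpart of [fit_mediation()] for a
#' simulation condition. Under the generating model (unit-variance residuals
#' for the mediators and Y, zero intercepts, independent mediator
#' residuals):
#' \itemize{
#'   \item single mediator: `Var(Y) = (ab + c')^2 Var(X) + b^2 + 1`
#'   \item two mediators: `Var(Y) = (a1 b1 + a2 b2 + c')^2 Var(X) + b1^2 + b2^2 + 1`
#' }
#' with `Var(X) = 1` for continuous X and `p(1-p)` for Bernoulli X.
#'
#' @param cond A [mediation_condition()].
#' @return A `path_estimates` object holding the population paths, the total
#'   effect `c = cprime + indirect`, and population `s_x`, `s_y`.
#' @examples
#' population_moments(mediation_condition(100, a = 0.39, b = 0.39, cprime = 0.39))
#' @export
population_moments <- function(cond) {
  cond <- as_condition(cond)
  p <- cond$paths
  var_x <- if (cond$x_type == "binary") cond$binary_p * (1 - cond$binary_p) else 1
  if (cond$n_mediators == 1L) {
    ind <- p[["a"]] * p[["b"]]
    var_y <- (ind + p[["cprime"]])^2 * var_x + p[["b"]]^2 + 1
    structure(list(
      a = p[["a"]], b = p[["b"]],
      c = p[["cprime"]] + ind, cprime = p[["cprime"]],
      intercepts = c(i1 = 0, i2 = 0, i3 = 0),
      residual_variances = c(eq2 = 1, eq3 = 1),
      s_x = sqrt(var_x), s_y = sqrt(var_y),
      n = cond$n, n_mediators = 1L, x_type = cond$x_type),
      class = "path_estimates")
  } else {
    ind <- p[["a1"]] * p[["b1"]] + p[["a2"]] * p[["b2"]]
    var_y <- (ind + p[["cprime"]])^2 * var_x + p[["b1"]]^2 + p[["b2"]]^2 + 1
    structure(list(
      a1 = p[["a1"]], b1 = p[["b1"]], a2 = p[["a2"]], b2 = p[["b2"]],
      c = p[["cprime"]] + ind, cprime = p[["cprime"]],
      intercepts = c(i1 = 0, i2 = 0, i3 = 0, i4 = 0),
      residual_variances = c(eq2 = 1, eq3 = 1, eq4 = 1),
      s_x = sqrt(var_x), s_y = sqrt(var_y),
      n = cond$n, n_mediators = 2L, x_type = cond$x_type),
      class = "path_estimates")
  }
}

#' True effect-size values for a simulation condition
#'
#' The estimands of the Monte Carlo studies: the four effect-size formulas
#' applied to the population paths with population standardizers from
#' [population_moments()]. The ratio is undefined (`NA`) at `cprime = 0`;
#' the proportion equals 1 at `cprime = 0` with a nonzero indirect effect
#' and is undefined when the total effect is zero.
#'
#' @param cond A [mediation_condition()].
#' @return An `effect_size_set`.
#' @export
true_effect_sizes <- function(cond) {
  effect_sizes(population_moments(cond))
}
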