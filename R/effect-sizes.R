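#' Indirect effect from fitted or population path coefficients
#'
#' The product of coefficients: `a*b` for one mediator, `a1*b1 + a2*b2` for
#' two parallel mediators. In linear OLS models this equals the difference
#' `c - c'` between the total and direct effects.
#'
#' @param paths A `path_estimates` object (from [fit_mediation()] or
#'   [population_moments()]).
#' @return The indirect effect, a single number.
#' @export
indirect_effect <- function(paths) {
  stopifnot(inherits(paths, "path_estimates"))
  if (paths$n_mediators == 1L) paths$a * paths$b else
    paths$a1 * paths$b1 + paths$a2 * paths$b2
}

#' Partially standardized indirect effect
#'
#' The indirect effect in standard-deviation units of the outcome:
#' `indirect / s_y`. For a binary exposure this is the shift, in SDs of Y,
#' attributable to mediation when moving between the two arms.
#'
#' @param indirect Indirect effect (e.g. [indirect_effect()]).
#' @param s_y Standard deviation of Y; must be positive.
#' @return `indirect / s_y`.
#' @export
partially_standardized <- function(indirect, s_y) {
  if (!is.finite(s_y) || s_y <= 0) stop("s_y must be positive")
  indirect / s_y
}

#' Fully standardized indirect effect
#'
#' The indirect effect in SD units of both variables:
#' `indirect * s_x / s_y` — the change, in SDs of Y, per SD increase in X.
#'
#' @inheritParams partially_standardized
#' @param s_x Standard deviation of X; must be positive.
#' @return `indirect * s_x / s_y`.
#' @export
fully_standardized <- function(indirect, s_x, s_y) {
  if (!is.finite(s_x) || s_x <= 0) stop("s_x must be positive")
  if (!is.finite(s_y) || s_y <= 0) stop("s_y must be positive")
  indirect * s_x / s_y
}

#' Proportion of the total effect that is mediated
#'
#' `indirect / (indirect + cprime)`. Undefined (returned as `NA`) when the
#' total effect is zero; equal to 1 under complete mediation (`cprime = 0`
#' with a nonzero indirect effect). Not clamped to \[0, 1\]: under
#' inconsistent mediation (direct and indirect effects of opposite sign)
#' the proportion can fall outside the unit interval.
#'
#' @inheritParams partially_standardized
#' @param cprime Direct effect.
#' @return The proportion mediated, or `NA` if the total effect is zero.
#' @export
proportion_mediated <- function(indirect, cprime) {
  total <- indirect + cprime
  if (total == 0) return(NA_real_)
  indirect / total
}

#' Ratio of the indirect to the direct effect
#'
#' `indirect / cprime`. Undefined (returned as `NA`) when the direct effect
#' is zero.
#'
#' @inheritParams proportion_mediated
#' @return The ratio mediated, or `NA` if `cprime` is zero.
#' @export
ratio_mediated <- function(indirect, cprime) {
  if (cprime == 0) return(NA_real_)
  indirect / cprime
}

#' All four effect-size measures from path coefficients
#'
#' Computes the indirect effect and the partially standardized, fully
#' standardized, proportion-mediated and ratio-mediated effect sizes,
#' carrying undefined values (`proportion` at zero total effect, `ratio` at
#' zero direct effect) as flagged `NA`s rather than errors.
#'
#' @param paths A `path_estimates` object; sample `s_x`/`s_y` are used when
#'   it comes from [fit_mediation()], population SDs when it comes from
#'   [population_moments()].
#' @return An object of class `effect_size_set`: list with `indirect`,
#'   `ab_ps`, `ab_fs`, `proportion`, `ratio` and a logical `defined` vector.
#' @examples
#' cond <- mediation_condition(n = 100, a = 0.39, b = 0.39, cprime = 0.39)
#' effect_sizes(fit_mediation(generate_dataset(cond, seed = 2)))
#' @export
effect_sizes <- function(paths) {
  stopifnot(inherits(paths, "path_estimates"))
  ind <- indirect_effect(paths)
  es <- list(
    indirect = ind,
    ab_ps = partially_standardized(ind, paths$s_y),
    ab_fs = fully_standardized(ind, paths$s_x, paths$s_y),
    proportion = proportion_mediated(ind, paths$cprime),
    ratio = ratio_mediated(ind, paths$cprime))
  es$defined <- !is.na(unlist(es[ES_NAMES]))
  structure(es, class = "effect_size_set")
}

ES_NAMES <- c("ab_ps", "ab_fs", "proportion", "ratio")

#' @export
print.effect_size_set <- function(x, digits = 4, ...) {
  cat("<effect_size_set>\n")
  v <- c(indirect = x$indirect, ab_ps = x$ab_ps, ab_fs = x$ab_fs,
         proportion = x$proportion, ratio = x$ratio)
  print(signif(v, digits))
  if (!all(x$defined))
    cat("  undefined:", paste(names(x$defined)[!x$defined], collapse = ", "),
        "\n")
  invisible(x)
}

#' @export
as.data.frame.effect_size_set <- function(x, ...) {
  data.frame(indirect = x$indirect, ab_ps = x$ab_ps, ab_fs = x$ab_fs,
             proportion = x$proportion, ratio = x$ratio)
}
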