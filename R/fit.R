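#' Ordinary least squares estimation of the mediation regressions
#'
#' `fit_single_mediator()` estimates the three single-mediator equations
#' (total effect Y ~ X, outcome Y ~ X + M, mediator M ~ X);
#' `fit_two_mediator()` estimates the four parallel two-mediator equations
#' (Y ~ X, Y ~ X + M1 + M2, M1 ~ X, M2 ~ X). `fit_mediation()` dispatches on
#' the number of mediators in `data`. All equations include intercepts.
#'
#' @param data A [mediation_data()] object.
#' @return An object of class `path_estimates`: a list with slopes (`a`,
#'   `b`, or `a1`, `b1`, `a2`, `b2`), the total effect `c`, the direct
#'   effect `cprime`, `intercepts`, `residual_variances` (one per equation,
#'   denominator n - p), sample standard deviations `s_x`, `s_y`
#'   (denominator n - 1), and `n_mediators`.
#' @examples
#' cond <- mediation_condition(n = 200, a = 0.5, b = 0.3, cprime = 0.2)
#' fit <- fit_mediation(generate_dataset(cond, seed = 7))
#' fit$c - (fit$cprime + fit$a * fit$b)   # OLS identity, ~0
#' @export
fit_mediation <- function(data) {
  stopifnot(inherits(data, "mediation_data"))
  if (data$n_mediators == 1L) fit_single_mediator(data) else
    fit_two_mediator(data)
}

check_full_rank <- function(fit, eq) {
  if (any(is.na(stats::coef(fit))))
    stop(sprintf("rank-deficient design in equation %s", eq))
}

resid_var <- function(fit) {
  r <- stats::residuals(fit)
  sum(r^2) / stats::df.residual(fit)
}

#' @rdname fit_mediation
#' @export
fit_single_mediator <- function(data) {
  stopifnot(inherits(data, "mediation_data"), data$n_mediators == 1L)
  x <- data$x; m <- data$mediators[[1]]; y <- data$y
  f1 <- stats::lm(y ~ x)
  f2 <- stats::lm(y ~ x + m)
  f3 <- stats::lm(m ~ x)
  check_full_rank(f1, "Y ~ X")
  check_full_rank(f2, "Y ~ X + M")
  check_full_rank(f3, "M ~ X")
  structure(list(
    a = unname(stats::coef(f3)["x"]),
    b = unname(stats::coef(f2)["m"]),
    c = unname(stats::coef(f1)["x"]),
    cprime = unname(stats::coef(f2)["x"]),
    intercepts = c(i1 = unname(stats::coef(f1)[1]),
                   i2 = unname(stats::coef(f2)[1]),
                   i3 = unname(stats::coef(f3)[1])),
    residual_variances = c(eq1 = resid_var(f1), eq2 = resid_var(f2),
                           eq3 = resid_var(f3)),
    s_x = stats::sd(x), s_y = stats::sd(y),
    n = data$n, n_mediators = 1L, x_type = data$x_type),
    class = "path_estimates")
}

#' @rdname fit_mediation
#' @export
fit_two_mediator <- function(data) {
  stopifnot(inherits(data, "mediation_data"), data$n_mediators == 2L)
  x <- data$x; m1 <- data$mediators[[1]]; m2 <- data$mediators[[2]]
  y <- data$y
  f1 <- stats::lm(y ~ x)
  f2 <- stats::lm(y ~ x + m1 + m2)
  f3 <- stats::lm(m1 ~ x)
  f4 <- stats::lm(m2 ~ x)
  check_full_rank(f1, "Y ~ X")
  check_full_rank(f2, "Y ~ X + M1 + M2")
  check_full_rank(f3, "M1 ~ X")
  check_full_rank(f4, "M2 ~ X")
  structure(list(
    a1 = unname(stats::coef(f3)["x"]),
    b1 = unname(stats::coef(f2)["m1"]),
    a2 = unname(stats::coef(f4)["x"]),
    b2 = unname(stats::coef(f2)["m2"]),
    c = unname(stats::coef(f1)["x"]),
    cprime = unname(stats::coef(f2)["x"]),
    intercepts = c(i1 = unname(stats::coef(f1)[1]),
                   i2 = unname(stats::coef(f2)[1]),
                   i3 = unname(stats::coef(f3)[1]),
                   i4 = unname(stats::coef(f4)[1])),
    residual_variances = c(eq1 = resid_var(f1), eq2 = resid_var(f2),
                           eq3 = resid_var(f3), eq4 = resid_var(f4)),
    s_x = stats::sd(x), s_y = stats::sd(y),
    n = data$n, n_mediators = 2L, x_type = data$x_type),
    class = "path_estimates")
}

#' @export
print.path_estimates <- function(x, digits = 4, ...) {
  cat(sprintf("<path_estimates> %d-mediator model, n = %d\n",
              x$n_mediators, x$n))
  sl <- if (x$n_mediators == 1L) c("a", "b", "c", "cprime") else
    c("a1", "b1", "a2", "b2", "c", "cprime")
  v <- vapply(sl, function(nm) x[[nm]], numeric(1))
  print(signif(v, digits))
  cat(sprintf("  s_x = %.4g, s_y = %.4g\n", x$s_x, x$s_y))
  invisible(x)
}

#' Write fitted coefficients to CSV
#'
#' One row per equation term (intercepts and slopes) plus one row per
#' residual variance and per sample standard deviation.
#'
#' @param fit A `path_estimates` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_path_estimates <- function(fit, path) {
  stopifnot(inherits(fit, "path_estimates"))
  sl <- if (fit$n_mediators == 1L) c("a", "b", "c", "cprime") else
    c("a1", "b1", "a2", "b2", "c", "cprime")
  rows <- rbind(
    data.frame(term = sl,
               value = vapply(sl, function(nm) fit[[nm]], numeric(1))),
    data.frame(term = names(fit$intercepts), value = unname(fit$intercepts)),
    data.frame(term = paste0("resid_var_", names(fit$residual_variances)),
               value = unname(fit$residual_variances)),
    data.frame(term = c("s_x", "s_y"), value = c(fit$s_x, fit$s_y)))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

# ---- vectorized moment-based OLS ------------------------------------------
# Columns of the input matrices are independent datasets (or resamples of
# one dataset). Slopes come from centered cross-products; identical to lm()
# with intercepts, but O(n) per column with no model-matrix overhead.

RANK_TOL <- 1e-10

# Single mediator: X, M, Y are n x K. Returns list of length-K vectors.
single_moment_estimates <- function(X, M, Y) {
  n <- nrow(X)
  sx <- .colSums(X, n, ncol(X)); sm <- .colSums(M, n, ncol(M))
  sy <- .colSums(Y, n, ncol(Y))
  cxx <- .colSums(X * X, n, ncol(X)) - sx * sx / n
  cmm <- .colSums(M * M, n, ncol(M)) - sm * sm / n
  cyy <- .colSums(Y * Y, n, ncol(Y)) - sy * sy / n
  cxm <- .colSums(X * M, n, ncol(X)) - sx * sm / n
  cxy <- .colSums(X * Y, n, ncol(X)) - sx * sy / n
  cmy <- .colSums(M * Y, n, ncol(M)) - sm * sy / n
  det <- cxx * cmm - cxm^2
  ok <- cxx > RANK_TOL & det > RANK_TOL
  list(a = cxm / cxx,
       b = (cxx * cmy - cxm * cxy) / det,
       cprime = (cmm * cxy - cxm * cmy) / det,
       c = cxy / cxx,
       s_x = sqrt(cxx / (n - 1)),
       s_y = sqrt(cyy / (n - 1)),
       ok = ok)
}

# Two parallel mediators: 3x3 normal equations solved by cofactors.
two_moment_estimates <- function(X, M1, M2, Y) {
  n <- nrow(X); k <- ncol(X)
  sx <- .colSums(X, n, k); s1 <- .colSums(M1, n, k)
  s2 <- .colSums(M2, n, k); sy <- .colSums(Y, n, k)
  cxx <- .colSums(X * X, n, k) - sx * sx / n
  c11 <- .colSums(M1 * M1, n, k) - s1 * s1 / n
  c22 <- .colSums(M2 * M2, n, k) - s2 * s2 / n
  cyy <- .colSums(Y * Y, n, k) - sy * sy / n
  cx1 <- .colSums(X * M1, n, k) - sx * s1 / n
  cx2 <- .colSums(X * M2, n, k) - sx * s2 / n
  c12 <- .colSums(M1 * M2, n, k) - s1 * s2 / n
  cxy <- .colSums(X * Y, n, k) - sx * sy / n
  c1y <- .colSums(M1 * Y, n, k) - s1 * sy / n
  c2y <- .colSums(M2 * Y, n, k) - s2 * sy / n
  # adjugate of the symmetric 3x3 Gram matrix [[cxx,cx1,cx2],[.,c11,c12],[.,.,c22]]
  adj11 <- c11 * c22 - c12^2
  adj12 <- cx2 * c12 - cx1 * c22
  adj13 <- cx1 * c12 - cx2 * c11
  adj22 <- cxx * c22 - cx2^2
  adj23 <- cx1 * cx2 - cxx * c12
  adj33 <- cxx * c11 - cx1^2
  det <- cxx * adj11 + cx1 * adj12 + cx2 * adj13
  ok <- cxx > RANK_TOL & det > RANK_TOL
  list(a1 = cx1 / cxx,
       a2 = cx2 / cxx,
       cprime = (adj11 * cxy + adj12 * c1y + adj13 * c2y) / det,
       b1 = (adj12 * cxy + adj22 * c1y + adj23 * c2y) / det,
       b2 = (adj13 * cxy + adj23 * c1y + adj33 * c2y) / det,
       c = cxy / cxx,
       s_x = sqrt(cxx / (n - 1)),
       s_y = sqrt(cyy / (n - 1)),
       ok = ok)
}

# Effect sizes from vectorized slope estimates; returns K x 5 matrix with
# columns indirect, ab_ps, ab_fs, proportion, ratio. NA encodes undefined.
moment_effect_sizes <- function(est, n_mediators) {
  ind <- if (n_mediators == 1L) est$a * est$b else
    est$a1 * est$b1 + est$a2 * est$b2
  total <- ind + est$cprime
  prop <- ifelse(total == 0, NA_real_, ind / total)
  ratio <- ifelse(est$cprime == 0, NA_real_, ind / est$cprime)
  out <- cbind(indirect = ind,
               ab_ps = ind / est$s_y,
               ab_fs = ind * est$s_x / est$s_y,
               proportion = prop,
               ratio = ratio)
  out[!est$ok, ] <- NA_real_
  out
}
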