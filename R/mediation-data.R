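#' Construct a mediation dataset
#'
#' Bundles the observed variables of a single- or parallel two-mediator
#' linear model: an exposure `x`, one or two mediators, and an outcome `y`.
#' All downstream estimation (OLS, bootstrap, Gibbs) consumes this container.
#'
#' @param x Numeric vector; the independent variable. For `x_type = "binary"`
#'   it must take at most two distinct values (conventionally 0/1).
#' @param m Numeric vector; the mediator (single-mediator model). Supply
#'   either `m`, or both `m1` and `m2`.
#' @param m1,m2 Numeric vectors; the two parallel mediators.
#' @param y Numeric vector; the dependent variable.
#' @param x_type Either `"continuous"` or `"binary"`.
#' @return An object of class `mediation_data`: a list with elements `x`,
#'   `mediators` (list of 1 or 2 vectors), `y`, `x_type`, `n` and
#'   `n_mediators`.
#' @examples
#' d <- mediation_data(x = rnorm(50), m = rnorm(50), y = rnorm(50))
#' d$n_mediators
#' @export
mediation_data <- function(x, m = NULL, m1 = NULL, m2 = NULL, y,
                           x_type = c("continuous", "binary")) {
  x_type <- match.arg(x_type)
  if (!is.null(m) && (!is.null(m1) || !is.null(m2)))
    stop("supply either `m` or `m1`+`m2`, not both")
  if (is.null(m) && (is.null(m1) || is.null(m2)))
    stop("supply `m` for one mediator or both `m1` and `m2` for two")
  mediators <- if (!is.null(m)) list(as.numeric(m)) else
    list(as.numeric(m1), as.numeric(m2))
  x <- as.numeric(x)
  y <- as.numeric(y)
  n <- length(x)
  lens <- c(n, lengths(mediators), length(y))
  if (length(unique(lens)) != 1L)
    stop("x, mediator(s) and y must all have the same length")
  n_med <- length(mediators)
  n_min <- if (n_med == 1L) 4L else 5L
  if (n < n_min)
    stop(sprintf("need at least %d observations for a %d-mediator model",
                 n_min, n_med))
  if (anyNA(x) || anyNA(y) || anyNA(unlist(mediators)))
    stop("missing values are not supported")
  if (x_type == "binary" && length(unique(x)) > 2L)
    stop("binary x may take at most 2 distinct values")
  structure(
    list(x = x, mediators = mediators, y = y, x_type = x_type,
         n = n, n_mediators = n_med),
    class = "mediation_data")
}

#' @export
print.mediation_data <- function(x, ...) {
  cat(sprintf("<mediation_data> n = %d, %d mediator(s), %s X\n",
              x$n, x$n_mediators, x$x_type))
  invisible(x)
}

#' Read a mediation dataset from delimited text
#'
#' Expects a header with columns `x`, `y` and either `m` (single mediator)
#' or `m1`, `m2` (two mediators). Field separator is inferred from the file
#' extension (`.tsv`/`.txt` = tab, otherwise comma) unless given.
#'
#' @param path Path to a CSV/TSV file.
#' @param x_type Passed to [mediation_data()].
#' @param sep Field separator; `NULL` to infer from the extension.
#' @return A `mediation_data` object.
#' @export
read_mediation_data <- function(path, x_type = c("continuous", "binary"),
                                sep = NULL) {
  x_type <- match.arg(x_type)
  if (is.null(sep))
    sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep)
  names(df) <- tolower(names(df))
  if (!all(c("x", "y") %in% names(df)))
    stop("input must have columns x and y")
  if ("m" %in% names(df)) {
    mediation_data(x = df$x, m = df$m, y = df$y, x_type = x_type)
  } else if (all(c("m1", "m2") %in% names(df))) {
    mediation_data(x = df$x, m1 = df$m1, m2 = df$m2, y = df$y, x_type = x_type)
  } else {
    stop("input must have a mediator column `m` or columns `m1` and `m2`")
  }
}

#' Specify a simulation condition
#'
#' A population configuration for the data-generating model: sample size,
#' path coefficients and the type of the independent variable. X has unit
#' variance when continuous (standard normal) or is Bernoulli(`binary_p`)
#' coded 0/1; mediator and outcome residuals have variance 1; intercepts are
#' zero.
#'
#' @param n Sample size (>= 10 for simulation use).
#' @param a,b Path values for the single-mediator model (X -> M and M -> Y).
#' @param a1,b1,a2,b2 Path values for the parallel two-mediator model.
#' @param cprime Direct effect of X on Y.
#' @param x_type `"continuous"` or `"binary"`.
#' @param binary_p Allocation probability for binary X (default 0.5,
#'   balanced two-arm allocation).
#' @return An object of class `mediation_condition`.
#' @examples
#' mediation_condition(n = 100, a = 0.39, b = 0.39, cprime = 0.39)
#' @export
mediation_condition <- function(n, a = NULL, b = NULL,
                                a1 = NULL, b1 = NULL, a2 = NULL, b2 = NULL,
                                cprime = 0,
                                x_type = c("continuous", "binary"),
                                binary_p = 0.5) {
  x_type <- match.arg(x_type)
  single <- !is.null(a) || !is.null(b)
  two <- !is.null(a1) || !is.null(b1) || !is.null(a2) || !is.null(b2)
  if (single && two) stop("supply a/b or a1/b1/a2/b2, not both")
  if (!single && !two) stop("supply path values a/b or a1/b1/a2/b2")
  if (n < 10) stop("simulation conditions require n >= 10")
  if (!(binary_p > 0 && binary_p < 1)) stop("binary_p must be in (0, 1)")
  paths <- if (single) {
    c(a = a %||% 0, b = b %||% 0, cprime = cprime)
  } else {
    c(a1 = a1 %||% 0, b1 = b1 %||% 0, a2 = a2 %||% 0, b2 = b2 %||% 0,
      cprime = cprime)
  }
  if (!all(is.finite(paths))) stop("path values must be finite")
  structure(
    list(n = as.integer(n), paths = paths,
         n_mediators = if (single) 1L else 2L,
         x_type = x_type, binary_p = binary_p),
    class = "mediation_condition")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.mediation_condition <- function(x, ...) {
  cat(sprintf("<mediation_condition> n = %d, %d mediator(s), %s X\n",
              x$n, x$n_mediators, x$x_type))
  cat("  paths:", paste(names(x$paths), signif(x$paths, 4),
                        sep = "=", collapse = ", "), "\n")
  invisible(x)
}

# Accept a mediation_condition or a 1-row data.frame (grid row).
as_condition <- function(cond) {
  if (inherits(cond, "mediation_condition")) return(cond)
  if (is.data.frame(cond) && nrow(cond) == 1L) {
    xt <- if ("x_type" %in% names(cond)) as.character(cond$x_type) else "continuous"
    bp <- if ("binary_p" %in% names(cond)) cond$binary_p else 0.5
    if ("a" %in% names(cond)) {
      return(mediation_condition(n = cond$n, a = cond$a, b = cond$b,
                                 cprime = cond$cprime, x_type = xt,
                                 binary_p = bp))
    }
    return(mediation_condition(n = cond$n, a1 = cond$a1, b1 = cond$b1,
                               a2 = cond$a2, b2 = cond$b2,
                               cprime = cond$cprime, x_type = xt,
                               binary_p = bp))
  }
  stop("cannot interpret `cond` as a simulation condition")
}

# Simulate `reps` independent datasets as n x reps matrices, sharing the
# caller's RNG stream. Returns list(x=, m=|m1=/m2=, y=).
simulate_matrices <- function(cond, reps) {
  cond <- as_condition(cond)
  n <- cond$n
  p <- cond$paths
  x <- if (cond$x_type == "binary") {
    matrix(stats::rbinom(n * reps, 1L, cond$binary_p), n, reps)
  } else {
    matrix(stats::rnorm(n * reps), n, reps)
  }
  if (cond$n_mediators == 1L) {
    m <- p[["a"]] * x + matrix(stats::rnorm(n * reps), n, reps)
    y <- p[["cprime"]] * x + p[["b"]] * m +
      matrix(stats::rnorm(n * reps), n, reps)
    list(x = x, m = m, y = y)
  } else {
    m1 <- p[["a1"]] * x + matrix(stats::rnorm(n * reps), n, reps)
    m2 <- p[["a2"]] * x + matrix(stats::rnorm(n * reps), n, reps)
    y <- p[["cprime"]] * x + p[["b1"]] * m1 + p[["b2"]] * m2 +
      matrix(stats::rnorm(n * reps), n, reps)
    list(x = x, m1 = m1, m2 = m2, y = y)
  }
}

#' Generate one dataset under a simulation condition
#'
#' Draws X (standard normal, or Bernoulli coded 0/1 for binary X), mediators
#' with unit-variance normal residuals, and Y with a unit-variance normal
#' residual, under the condition's population path values and zero
#' intercepts. Deterministic given `seed`.
#'
#' @param cond A [mediation_condition()] (or 1-row grid data.frame).
#' @param seed Integer seed.
#' @return A `mediation_data` object.
#' @examples
#' cond <- mediation_condition(n = 50, a = 0.39, b = 0.39, cprime = 0.39)
#' d <- generate_dataset(cond, seed = 1)
#' @export
generate_dataset <- function(cond, seed) {
  cond <- as_condition(cond)
  set.seed(as.integer(seed))
  sim <- simulate_matrices(cond, 1L)
  if (cond$n_mediators == 1L) {
    mediation_data(x = sim$x[, 1], m = sim$m[, 1], y = sim$y[, 1],
                   x_type = cond$x_type)
  } else {
    mediation_data(x = sim$x[, 1], m1 = sim$m1[, 1], m2 = sim$m2[, 1],
                   y = sim$y[, 1], x_type = cond$x_type)
  }
}
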