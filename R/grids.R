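#' Simulation condition grids
#'
#' `single_mediator_grid()` crosses sample sizes with all combinations of
#' the `a`, `b` and `cprime` path values 0, 0.14, 0.39, 0.59 (zero, small,
#' medium, large effects): 5 x 4^3 = 320 conditions for the point study
#' (n = 10, 50, 100, 500, 1000) and 4 x 4^3 = 256 for the interval study
#' (n = 50, 100, 500, 1000).
#'
#' `two_mediator_grid()` uses path values 0, 0.101, 0.314, 0.577 for the
#' mediated paths and 0, 0.131, 0.4, 0.74 for `cprime`, constrained to
#' `a1 = b1` and `a2 = b2`, crossed with n = 10, 50, 100, 500:
#' 4 x 4 x 4 x 4 = 256 conditions.
#'
#' @param study `"point"` or `"interval"` (selects the sample-size list for
#'   the single-mediator grid).
#' @param x_type `"continuous"` or `"binary"`.
#' @param n Optional sample-size vector overriding the default list.
#' @return A data.frame with one row per condition: `n`, path columns and
#'   `x_type`.
#' @export
single_mediator_grid <- function(study = c("point", "interval"),
                                 x_type = c("continuous", "binary"),
                                 n = NULL) {
  study <- match.arg(study)
  x_type <- match.arg(x_type)
  if (is.null(n))
    n <- if (study == "point") c(10L, 50L, 100L, 500L, 1000L) else
      c(50L, 100L, 500L, 1000L)
  paths <- c(0, 0.14, 0.39, 0.59)
  g <- expand.grid(cprime = paths, b = paths, a = paths, n = n,
                   KEEP.OUT.ATTRS = FALSE)
  g <- g[, c("n", "a", "b", "cprime")]
  g$x_type <- x_type
  rownames(g) <- NULL
  g
}

#' @rdname single_mediator_grid
#' @export
two_mediator_grid <- function(x_type = c("continuous", "binary"), n = NULL) {
  x_type <- match.arg(x_type)
  if (is.null(n)) n <- c(10L, 50L, 100L, 500L)
  ab <- c(0, 0.101, 0.314, 0.577)
  cp <- c(0, 0.131, 0.4, 0.74)
  g <- expand.grid(cprime = cp, ab2 = ab, ab1 = ab, n = n,
                   KEEP.OUT.ATTRS = FALSE)
  out <- data.frame(n = g$n, a1 = g$ab1, b1 = g$ab1, a2 = g$ab2, b2 = g$ab2,
                    cprime = g$cprime, x_type = x_type)
  rownames(out) <- NULL
  out
}

#' Conditions for the Bayesian simulation study
#'
#' The parameter combinations at which the frequentist estimators showed
#' excessive relative bias at n = 50: 17 single-mediator conditions (6 with
#' continuous X, 11 with binary X) and 21 two-mediator conditions (11
#' continuous, 10 binary), all at n = 50.
#'
#' @param model `"single"` or `"two"`.
#' @param x_type `"continuous"`, `"binary"` or `"both"` (default).
#' @return A data.frame of conditions (n = 50 throughout).
#' @export
bayes_study_conditions <- function(model = c("single", "two"),
                                   x_type = c("both", "continuous",
                                              "binary")) {
  model <- match.arg(model)
  x_type <- match.arg(x_type)
  if (model == "single") {
    cont <- rbind(
      c(0.14, 0.14, 0),
      c(0.14, 0.39, 0.14),
      c(0.14, 0.14, 0.39), c(0.14, 0.59, 0.39), c(0.39, 0.39, 0.39),
      c(0.14, 0.59, 0.59))
    bin <- rbind(
      c(0.14, 0.39, 0), c(0.39, 0.39, 0),
      c(0.14, 0.14, 0.14), c(0.14, 0.39, 0.14), c(0.14, 0.59, 0.14),
      c(0.39, 0.14, 0.14),
      c(0.14, 0.39, 0.39), c(0.39, 0.14, 0.39), c(0.59, 0.14, 0.39),
      c(0.14, 0.39, 0.59), c(0.39, 0.59, 0.59))
    mk <- function(m, xt) data.frame(n = 50L, a = m[, 1], b = m[, 2],
                                     cprime = m[, 3], x_type = xt)
    out <- rbind(mk(cont, "continuous"), mk(bin, "binary"))
  } else {
    # columns: a1 = b1, a2 = b2, cprime
    cont <- rbind(
      c(0, 0.101, 0), c(0.101, 0, 0), c(0.101, 0.101, 0),
      c(0, 0.314, 0.131), c(0.101, 0, 0.131),
      c(0, 0.101, 0.4), c(0.101, 0, 0.4),
      c(0, 0.101, 0.74), c(0.101, 0, 0.74), c(0.101, 0.101, 0.74),
      c(0.314, 0.101, 0.74))
    bin <- rbind(
      c(0, 0.101, 0), c(0.101, 0, 0), c(0.314, 0.101, 0),
      c(0.101, 0, 0.131),
      c(0, 0.101, 0.4), c(0.101, 0, 0.4), c(0.101, 0.101, 0.4),
      c(0, 0.101, 0.74), c(0.101, 0, 0.74), c(0.101, 0.101, 0.74))
    mk <- function(m, xt) data.frame(n = 50L, a1 = m[, 1], b1 = m[, 1],
                                     a2 = m[, 2], b2 = m[, 2],
                                     cprime = m[, 3], x_type = xt)
    out <- rbind(mk(cont, "continuous"), mk(bin, "binary"))
  }
  if (x_type != "both") out <- out[out$x_type == x_type, ]
  rownames(out) <- NULL
  out
}
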