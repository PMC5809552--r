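CONFIG_DEFAULTS <- list(
  study = NULL,            # "point", "interval" or "bayes" (required)
  model = "single",        # "single" or "two"
  x_type = "continuous",   # "continuous" or "binary"
  n = NULL,                # optional sample-size override for the grids
  reps = 1000L,
  B = 1000L,
  level = 0.95,
  n_iter = 11000L,
  burn_in = 1000L,
  seed = 1L,
  out = NULL,              # optional output path
  format = "csv",
  verbose = FALSE)

#' Load and validate a study configuration
#'
#' Reads a JSON configuration for [run_study()]. Unknown keys are rejected;
#' missing keys are filled with defaults; every violation found is reported
#' in a single error message.
#'
#' @param path Path to a JSON file.
#' @return A validated `study_config` (named list).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.list(raw)) stop("config must be a JSON object")
  problems <- character()
  unknown <- setdiff(names(raw), names(CONFIG_DEFAULTS))
  if (length(unknown) > 0L)
    problems <- c(problems,
                  sprintf("unknown key(s): %s", paste(unknown, collapse = ", ")))
  cfg <- utils::modifyList(CONFIG_DEFAULTS, raw[setdiff(names(raw), unknown)])
  chk <- function(ok, msg) if (!isTRUE(ok)) problems <<- c(problems, msg)
  chk(!is.null(cfg$study) && cfg$study %in% c("point", "interval", "bayes"),
      "`study` must be one of: point, interval, bayes")
  chk(cfg$model %in% c("single", "two"), "`model` must be single or two")
  chk(cfg$x_type %in% c("continuous", "binary"),
      "`x_type` must be continuous or binary")
  chk(is.numeric(cfg$reps) && length(cfg$reps) == 1L && cfg$reps >= 2,
      "`reps` must be a single number >= 2")
  chk(is.numeric(cfg$B) && length(cfg$B) == 1L && cfg$B >= 100,
      "`B` must be a single number >= 100")
  chk(is.numeric(cfg$level) && cfg$level > 0 && cfg$level < 1,
      "`level` must be in (0, 1)")
  chk(is.numeric(cfg$n_iter) && is.numeric(cfg$burn_in) &&
        cfg$n_iter > cfg$burn_in, "`n_iter` must exceed `burn_in`")
  chk(is.numeric(cfg$seed) && length(cfg$seed) == 1L,
      "`seed` must be a single integer")
  if (!is.null(cfg$n))
    chk(is.numeric(cfg$n) && all(cfg$n >= 10),
        "`n` must be numeric with all values >= 10")
  chk(cfg$format %in% c("csv", "tsv"), "`format` must be csv or tsv")
  if (length(problems) > 0L)
    stop(paste(c("invalid configuration:", problems), collapse = "\n  - "))
  structure(cfg, class = "study_config")
}

#' Run a configured Monte Carlo study
#'
#' Dispatches a validated configuration to [run_point_study()],
#' [run_interval_study()] or [run_bayes_study()] on the matching default
#' grid, logging the package version, master seed and configuration hash so
#' the run is reproducible from the log header alone.
#'
#' @param config A `study_config` from [load_config()], or a path to one.
#' @return The study's metrics data.frame (also written to `config$out` via
#'   [write_results()] when set).
#' @export
run_study <- function(config) {
  if (is.character(config)) config <- load_config(config)
  stopifnot(inherits(config, "study_config"))
  hash <- sum(utf8ToInt(paste(names(config),
                              vapply(config, function(x)
                                paste(format(x), collapse = ","), ""),
                              collapse = ";"))) %% 1000000L
  message(sprintf("medfx %s | study=%s model=%s x=%s seed=%d | config#%06d",
                  as.character(utils::packageVersion("medfx")),
                  config$study, config$model, config$x_type,
                  as.integer(config$seed), hash))
  grid <- switch(config$model,
    single = single_mediator_grid(
      study = if (config$study == "interval") "interval" else "point",
      x_type = config$x_type, n = config$n),
    two = two_mediator_grid(x_type = config$x_type, n = config$n))
  res <- switch(config$study,
    point = run_point_study(grid, reps = config$reps, seed = config$seed),
    interval = run_interval_study(grid, reps = config$reps, B = config$B,
                                  level = config$level, seed = config$seed),
    bayes = run_bayes_study(
      conditions = bayes_study_conditions(config$model, config$x_type),
      reps = config$reps, n_iter = config$n_iter, burn_in = config$burn_in,
      level = config$level, seed = config$seed))
  if (!is.null(config$out))
    write_results(res, config$out, format = config$format)
  res
}

#' Worked examples from the steroid-prevention trial coefficients
#'
#' Reproduces the frequentist point estimates of the published worked
#' examples from their printed coefficients (the raw n = 1315 dataset is
#' not public, so only printed-coefficient arithmetic is possible; the
#' interval and posterior columns of those tables are not reproducible).
#' `"table3"` is the single-mediator example (a = 0.549, b = 0.174,
#' c' = 0.234, s_Y = 1.217); `"table4"` the two-mediator example
#' (a1 = 0.549, b1 = 0.165, a2 = 0.440, b2 = 0.092, c' = 0.188,
#' s_Y = 1.217). X is a binary treatment indicator, so the fully
#' standardized measure is not part of the published tables.
#'
#' @param which `"table3"` or `"table4"`.
#' @return A list: `indirect`, `ab_ps`, `proportion`, `ratio`.
#' @examples
#' worked_example("table3")   # ab_ps 0.078, proportion 0.290, ratio 0.408
#' @export
worked_example <- function(which = c("table3", "table4")) {
  which <- match.arg(which)
  if (which == "table3") {
    ind <- 0.549 * 0.174
    cprime <- 0.234
  } else {
    ind <- 0.549 * 0.165 + 0.440 * 0.092
    cprime <- 0.188
  }
  s_y <- 1.217
  list(indirect = ind,
       ab_ps = partially_standardized(ind, s_y),
       proportion = proportion_mediated(ind, cprime),
       ratio = ratio_mediated(ind, cprime))
}

#' Write a metrics table to delimited text
#'
#' Writes at full floating-point precision; undefined values are serialized
#' as the sentinel `NA` and re-parsed as undefined by [read_results()].
#'
#' @param table A non-empty data.frame.
#' @param path Output path.
#' @param format `"csv"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_results <- function(table, path, format = c("csv", "tsv")) {
  format <- match.arg(format)
  if (!is.data.frame(table) || nrow(table) == 0L)
    stop("`table` must be a non-empty data.frame")
  sep <- if (format == "csv") "," else "\t"
  utils::write.table(table, path, sep = sep, row.names = FALSE,
                     na = "NA", qmethod = "double")
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path, format = c("csv", "tsv")) {
  format <- match.arg(format)
  sep <- if (format == "csv") "," else "\t"
  utils::read.table(path, header = TRUE, sep = sep, na.strings = "NA",
                    stringsAsFactors = FALSE)
}
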