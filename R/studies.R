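# Per-condition seeds derived from one master seed, so any condition can be
# re-run in isolation; kept below 2^31.
condition_seeds <- function(seed, k) {
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, k)
}

condition_label <- function(row) {
  pcols <- intersect(c("a", "b", "a1", "b1", "a2", "b2", "cprime"),
                     names(row))
  paste0("n=", row$n, ";",
         paste(pcols, unlist(row[pcols]), sep = "=", collapse = ";"),
         ";x=", row$x_type)
}

# Simulate `reps` replication datasets for one condition and return the
# reps x 5 matrix of OLS effect-size estimates, regenerating replications
# whose design is rank-deficient (possible for binary X at small n).
replication_estimates <- function(cond, reps, max_rounds = 100L) {
  est_of <- function(sim) {
    if (cond$n_mediators == 1L)
      single_moment_estimates(sim$x, sim$m, sim$y)
    else
      two_moment_estimates(sim$x, sim$m1, sim$m2, sim$y)
  }
  sim <- simulate_matrices(cond, reps)
  est <- est_of(sim)
  values <- moment_effect_sizes(est, cond$n_mediators)
  bad <- which(!est$ok)
  n_regen <- 0L
  rounds <- 0L
  while (length(bad) > 0L) {
    rounds <- rounds + 1L
    if (rounds > max_rounds)
      stop("systematically singular designs for condition; giving up")
    n_regen <- n_regen + length(bad)
    sim2 <- simulate_matrices(cond, length(bad))
    est2 <- est_of(sim2)
    values[bad, ] <- moment_effect_sizes(est2, cond$n_mediators)
    bad <- bad[!est2$ok]
  }
  list(values = values, n_regenerated = n_regen)
}

#' Monte Carlo study of point-estimate bias and efficiency
#'
#' For every condition in `grid`: simulates `reps` datasets, fits the
#' mediation regressions by OLS, computes the four effect sizes, and
#' aggregates bias, relative bias, SD (efficiency) and standardized bias
#' against the population values from [true_effect_sizes()]. Replications
#' with rank-deficient designs are regenerated from the condition's RNG
#' stream and counted. Fully deterministic given `seed`.
#'
#' @param grid Conditions data.frame ([single_mediator_grid()],
#'   [two_mediator_grid()], or any data.frame with the same columns).
#' @param reps Replications per condition (>= 2; the reference studies use
#'   1000).
#' @param seed Master seed; per-condition seeds are derived from it.
#' @return A data.frame with one row per condition x estimator: the
#'   condition columns, `estimator`, `truth`, `bias`, `relative_bias`,
#'   `sd`, `standardized_bias`, `relbias_flag` (TRUE when
#'   `|relative_bias| > 0.05`), `reps_used`, `reps_undefined`,
#'   `n_regenerated`.
#' @examples
#' g <- single_mediator_grid()[c(30, 200), ]
#' run_point_study(g, reps = 50, seed = 1)
#' @export
run_point_study <- function(grid, reps = 1000L, seed = 1L) {
  stopifnot(is.data.frame(grid), nrow(grid) >= 1L, reps >= 2L)
  seeds <- condition_seeds(seed, nrow(grid))
  out <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    row <- grid[i, , drop = FALSE]
    cond <- as_condition(row)
    truth <- true_effect_sizes(cond)
    set.seed(seeds[i])
    rep_est <- replication_estimates(cond, as.integer(reps))
    recs <- lapply(ES_NAMES, function(nm) {
      pm <- point_metrics(rep_est$values[, nm], truth[[nm]])
      cbind(row, data.frame(
        condition = condition_label(row), estimator = nm,
        truth = truth[[nm]], bias = pm$bias,
        relative_bias = pm$relative_bias, sd = pm$sd,
        standardized_bias = pm$standardized_bias,
        relbias_flag = !is.na(pm$relative_bias) &
          abs(pm$relative_bias) > 0.05,
        reps_used = pm$reps_used, reps_undefined = pm$reps_undefined,
        n_regenerated = rep_est$n_regenerated, row.names = NULL))
    })
    out[[i]] <- do.call(rbind, recs)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Build a mediation_data object from one simulated column without
# re-validating (inputs come from the package's own generator).
as_mediation_data <- function(cond, sim, j = 1L) {
  if (cond$n_mediators == 1L) {
    structure(list(x = sim$x[, j], mediators = list(sim$m[, j]),
                   y = sim$y[, j], x_type = cond$x_type, n = cond$n,
                   n_mediators = 1L), class = "mediation_data")
  } else {
    structure(list(x = sim$x[, j],
                   mediators = list(sim$m1[, j], sim$m2[, j]),
                   y = sim$y[, j], x_type = cond$x_type, n = cond$n,
                   n_mediators = 2L), class = "mediation_data")
  }
}

#' Monte Carlo study of bootstrap interval estimators
#'
#' For every condition: per replication, simulates a dataset, draws `B`
#' case resamples (shared across the four effect sizes), and builds the
#' requested bootstrap intervals; aggregates power/Type I error, coverage,
#' mean width and imbalance via [interval_metrics()], with Bradley
#' robustness classifications attached.
#'
#' @inheritParams run_point_study
#' @param B Bootstrap resamples per interval (>= 100).
#' @param methods Subset of `c("percentile", "bias_corrected")`.
#' @param level Nominal coverage.
#' @return A data.frame with one row per condition x estimator x method:
#'   condition columns, `estimator`, `method`, `truth`, `rate`,
#'   `rate_type`, `bradley_rate` (Type I classification, `NA` for power
#'   rows), `coverage`, `bradley_coverage`, `width_mean`, `imbalance`,
#'   `reps_used`, `reps_undefined`.
#' @examples
#' g <- data.frame(n = 50, a = 0, b = 0, cprime = 0.14,
#'                 x_type = "continuous")
#' run_interval_study(g, reps = 5, B = 100, seed = 1)
#' @export
run_interval_study <- function(grid, reps = 1000L, B = 1000L,
                               methods = c("percentile", "bias_corrected"),
                               level = 0.95, seed = 1L) {
  stopifnot(is.data.frame(grid), nrow(grid) >= 1L, reps >= 2L, B >= 100L)
  methods <- match.arg(methods, several.ok = TRUE)
  reps <- as.integer(reps); B <- as.integer(B)
  seeds <- condition_seeds(seed, nrow(grid))
  out <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    row <- grid[i, , drop = FALSE]
    cond <- as_condition(row)
    truth <- true_effect_sizes(cond)
    set.seed(seeds[i])
    lims <- array(NA_real_,
                  dim = c(reps, length(ES_NAMES), length(methods), 2L),
                  dimnames = list(NULL, ES_NAMES, methods,
                                  c("lower", "upper")))
    for (r in seq_len(reps)) {
      # regenerate datasets whose full-sample design is rank-deficient
      for (attempt in seq_len(100L)) {
        sim <- simulate_matrices(cond, 1L)
        data_r <- as_mediation_data(cond, sim)
        obs <- tryCatch(observed_effect_sizes(data_r),
                        error = function(e) NULL)
        if (!is.null(obs)) break
        if (attempt == 100L) stop("could not generate a full-rank dataset")
      }
      bm <- boot_effect_size_matrix(data_r, B)
      for (nm in ES_NAMES) {
        v <- bm$values[, nm]
        if ("percentile" %in% methods) {
          int <- percentile_interval(v, level)
          lims[r, nm, "percentile", ] <- c(int$lower, int$upper)
        }
        if ("bias_corrected" %in% methods) {
          int <- if (is.na(obs[[nm]]))
            interval_estimate(NA_real_, NA_real_, level, "bias_corrected")
          else suppressWarnings(
            bias_corrected_interval(v, level, observed = obs[[nm]]))
          lims[r, nm, "bias_corrected", ] <- c(int$lower, int$upper)
        }
      }
    }
    recs <- list()
    for (nm in ES_NAMES) {
      for (mth in methods) {
        im <- interval_metrics(lims[, nm, mth, "lower"],
                               lims[, nm, mth, "upper"], truth[[nm]])
        recs[[length(recs) + 1L]] <- cbind(row, data.frame(
          condition = condition_label(row), estimator = nm, method = mth,
          truth = truth[[nm]], rate = im$rate, rate_type = im$rate_type,
          bradley_rate = if (identical(im$rate_type, "type1"))
            bradley_assess(im$rate, "type1") else NA_character_,
          coverage = im$coverage,
          bradley_coverage = if (is.na(im$coverage)) NA_character_ else
            bradley_assess(im$coverage, "coverage"),
          width_mean = im$width_mean, imbalance = im$imbalance,
          reps_used = im$reps_used, reps_undefined = im$reps_undefined,
          row.names = NULL))
      }
    }
    out[[i]] <- do.call(rbind, recs)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Monte Carlo study of Bayesian point and interval summaries
#'
#' For every condition (by default the n = 50 lists of conditions where
#' frequentist relative bias was excessive, see
#' [bayes_study_conditions()]): per replication, simulates a dataset, runs
#' the Gibbs sampler, and records the posterior mean and median of each
#' effect size (plus the frequentist OLS estimate for comparison) and
#' whether the equal-tail and HPD intervals cover the truth. Aggregates
#' relative bias per point summary and coverage per interval type.
#'
#' @inheritParams run_point_study
#' @param conditions Conditions data.frame; default
#'   `bayes_study_conditions(model)`.
#' @param model `"single"` or `"two"`; used only to pick the default
#'   condition list.
#' @param priors A [prior_spec()].
#' @param n_iter,burn_in Gibbs chain length per replication.
#' @param level Credibility level.
#' @param rhat_max Convergence threshold on the split-chain potential scale
#'   reduction; replications with any path above it are counted in
#'   `n_nonconverged` (but retained).
#' @return A data.frame, one row per condition x estimator, with relative
#'   bias of the posterior mean, posterior median and frequentist estimate,
#'   coverage of equal-tail and HPD intervals, Bradley classifications of
#'   both coverages, and replication accounting.
#' @examples
#' conds <- bayes_study_conditions("single")[1, ]
#' run_bayes_study(conds, reps = 2, n_iter = 300, burn_in = 50, seed = 1)
#' @export
run_bayes_study <- function(conditions = NULL, model = c("single", "two"),
                            reps = 1000L, priors = prior_spec(),
                            n_iter = 11000L, burn_in = 1000L, level = 0.95,
                            rhat_max = 1.1, seed = 1L) {
  model <- match.arg(model)
  if (is.null(conditions)) conditions <- bayes_study_conditions(model)
  stopifnot(is.data.frame(conditions), nrow(conditions) >= 1L, reps >= 2L)
  reps <- as.integer(reps)
  seeds <- condition_seeds(seed, nrow(conditions))
  out <- vector("list", nrow(conditions))
  for (i in seq_len(nrow(conditions))) {
    row <- conditions[i, , drop = FALSE]
    cond <- as_condition(row)
    truth <- true_effect_sizes(cond)
    set.seed(seeds[i])
    pm <- array(NA_real_, dim = c(reps, length(ES_NAMES), 3L),
                dimnames = list(NULL, ES_NAMES,
                                c("post_mean", "post_median", "freq")))
    cov <- array(NA, dim = c(reps, length(ES_NAMES), 2L),
                 dimnames = list(NULL, ES_NAMES, c("equal_tail", "hpd")))
    n_nonconv <- 0L
    for (r in seq_len(reps)) {
      for (attempt in seq_len(100L)) {
        sim <- simulate_matrices(cond, 1L)
        data_r <- as_mediation_data(cond, sim)
        obs <- tryCatch(observed_effect_sizes(data_r),
                        error = function(e) NULL)
        if (!is.null(obs)) break
        if (attempt == 100L) stop("could not generate a full-rank dataset")
      }
      post <- gibbs_mediation(data_r, priors = priors, n_iter = n_iter,
                              burn_in = burn_in)
      if (any(post$rhat > rhat_max, na.rm = TRUE))
        n_nonconv <- n_nonconv + 1L
      es <- effect_size_draws(post)
      for (nm in ES_NAMES) {
        v <- es[, nm]
        pm[r, nm, "post_mean"] <- posterior_point(v, "mean")
        pm[r, nm, "post_median"] <- posterior_point(v, "median")
        pm[r, nm, "freq"] <- obs[[nm]]
        if (!is.na(truth[[nm]])) {
          et <- equal_tail_interval(v, level)
          hp <- hpd_interval(v, level)
          if (et$defined)
            cov[r, nm, "equal_tail"] <-
              et$lower <= truth[[nm]] && truth[[nm]] <= et$upper
          if (hp$defined)
            cov[r, nm, "hpd"] <-
              hp$lower <= truth[[nm]] && truth[[nm]] <= hp$upper
        }
      }
    }
    recs <- lapply(ES_NAMES, function(nm) {
      rb <- function(col) point_metrics(pm[, nm, col],
                                        truth[[nm]])$relative_bias
      cov_et <- mean(cov[, nm, "equal_tail"], na.rm = TRUE)
      cov_hpd <- mean(cov[, nm, "hpd"], na.rm = TRUE)
      if (is.nan(cov_et)) cov_et <- NA_real_
      if (is.nan(cov_hpd)) cov_hpd <- NA_real_
      cbind(row, data.frame(
        condition = condition_label(row), estimator = nm,
        truth = truth[[nm]],
        relbias_post_mean = rb("post_mean"),
        relbias_post_median = rb("post_median"),
        relbias_freq = rb("freq"),
        coverage_equal_tail = cov_et,
        coverage_hpd = cov_hpd,
        bradley_equal_tail = if (is.na(cov_et)) NA_character_ else
          bradley_assess(cov_et, "coverage"),
        bradley_hpd = if (is.na(cov_hpd)) NA_character_ else
          bradley_assess(cov_hpd, "coverage"),
        reps_used = reps, n_nonconverged = n_nonconv, row.names = NULL))
    })
    out[[i]] <- do.call(rbind, recs)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
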