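# Independent reference implementations used as oracles; they never call
# the package's own interval/estimation code paths.

# Bias-corrected bootstrap limits by direct normal-quantile arithmetic.
reference_bc <- function(draws, observed, level) {
  nd <- length(draws)
  p_below <- (sum(draws < observed) + 0.5 * sum(draws == observed)) / nd
  z0 <- qnorm(p_below)
  alpha <- 1 - level
  sorted <- sort(draws)
  k <- function(p) min(max(ceiling(pnorm(2 * z0 + qnorm(p)) * nd - 1e-9), 1), nd)
  c(sorted[k(alpha / 2)], sorted[k(1 - alpha / 2)])
}

# Exhaustive search over every contiguous run of sorted draws containing at
# least ceiling(level * n) points; minimal width, ties to the lowest lower
# bound.
reference_hpd <- function(draws, level) {
  sorted <- sort(draws)
  n <- length(sorted)
  m <- ceiling(level * n - 1e-9)
  best <- c(-Inf, Inf)
  for (i in seq_len(n)) {
    for (j in seq(i, n)) {
      if (j - i + 1 >= m) {
        w <- sorted[j] - sorted[i]
        if (w < (best[2] - best[1]) - 1e-15) best <- c(sorted[i], sorted[j])
      }
    }
  }
  best
}

# Monte Carlo standard error of a chain mean by non-overlapping batch means.
batch_mcse <- function(v, n_batch = 20) {
  m <- floor(length(v) / n_batch)
  means <- vapply(seq_len(n_batch),
                  function(k) mean(v[((k - 1) * m + 1):(k * m)]), 0)
  sd(means) / sqrt(n_batch)
}

# A small single-mediator dataset with exactly recoverable paths: the
# mediator residual is orthogonal to x with mean zero, and y has no
# residual, so OLS returns a = 0.5, b = 0.3, c' = 0.2 exactly.
noiseless_single <- function() {
  x <- c(1, -1, 2, -2)
  e <- c(1, 1, -1, -1)            # sum(e) = 0, sum(x * e) = 0
  m <- 0.5 * x + e
  y <- 0.2 * x + 0.3 * m
  mediation_data(x = x, m = m, y = y)
}

noiseless_two <- function() {
  x <- c(1, -1, 2, -2, 0, 0)
  e1 <- c(1, 1, -1, -1, 2, -2)    # orthogonal to x, mean zero
  e2 <- c(1, 1, -1, -1, -2, 2)    # orthogonal to x and not collinear with e1
  m1 <- 0.3 * x + e1
  m2 <- 0.1 * x + e2
  y <- 0.4 * x + 0.3 * m1 + 0.1 * m2
  mediation_data(x = x, m1 = m1, m2 = m2, y = y)
}
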