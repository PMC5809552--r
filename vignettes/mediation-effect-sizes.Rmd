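---
title: "Effect-size measures for mediation models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Effect-size measures for mediation models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(medfx)
```

## The models

medfx works with two linear mediation models. In the single-mediator model
an exposure X influences an outcome Y partly through a mediator M:

* Y = i1 + c X + e1 (total effect)
* Y = i2 + c' X + b M + e2 (direct effect and mediator slope)
* M = i3 + a X + e3 (exposure-to-mediator path)

In the parallel two-mediator model the middle equation gains a second
mediator (Y = i2 + c' X + b1 M1 + b2 M2 + e2) and each mediator gets its
own equation (Mj = i + aj X + e). The indirect (mediated) effect is the
product of coefficients, ab, or the sum of products, a1 b1 + a2 b2; in
linear OLS models it coincides with c − c', and `fit_mediation()` satisfies
that identity to machine precision, which the test suite asserts at 1e-10.

## The four effect sizes

Raw indirect effects carry the units of X and Y, which are often
arbitrary. The package computes four unit-free summaries:

| measure      | formula                  | undefined when      |
|--------------|--------------------------|---------------------|
| `ab_ps`      | indirect / s_Y           | never (s_Y > 0)     |
| `ab_fs`      | indirect × s_X / s_Y     | never               |
| `proportion` | indirect / (indirect + c') | total effect = 0  |
| `ratio`      | indirect / c'            | c' = 0              |

Undefinedness is a *value*, not an exception: the estimation and
simulation code carries flagged `NA`s through every aggregation step, so
grids that include c' = 0 cells keep running. The proportion is
deliberately not clamped to [0, 1] — under inconsistent mediation (direct
and indirect effects of opposite sign) it legitimately leaves the unit
interval, and the ratio's documented instability (interval widths in the
thousands at small n) is part of what the harness is meant to expose, so
no trimming or winsorizing is applied anywhere.

Estimated effect sizes use the sample standard deviations (denominator
n − 1); true (estimand) values use the model-implied population moments:
Var(Y) = (indirect + c')² Var(X) + Σ b² + 1, with Var(X) = 1 for
continuous X and p(1 − p) for binary X. This estimator-versus-estimand
separation is what bias and coverage are measured against.

## Interval estimators

**Percentile bootstrap.** `B` case resamples of size n; the interval is
formed from the ceiling-rule order statistics at α/2 and 1 − α/2 of the
*defined* draws. Endpoints are realized draws (no interpolation), which
makes the construction equivariant under monotone transforms and exactly
reproducible. `B` defaults to 1000 — a conventional choice; the reference
studies do not state theirs.

**Bias-corrected bootstrap.** The correction z0 = Φ⁻¹(p) uses the
proportion p of draws *below* the observed estimate, with ties counted
half. (Descriptions of this method sometimes speak of the proportion that
*exceeds* the observed value; the two conventions flip the sign of z0 and
the standard construction used here is the one matching the quoted
endpoint formula Φ(2 z0 + z_{α/2}).) When every draw falls on one side of
the observed value, z0 is clamped to Φ⁻¹(1/(B+1)) or Φ⁻¹(B/(B+1)) with a
warning rather than ±∞.

Resamples with rank-deficient designs — a real possibility for binary X at
small n, when a resample can drop one arm entirely — are redrawn from the
same RNG stream (bounded at 100 rounds) and counted in `n_redrawn`, rather
than silently dropped or allowed to poison the draw set.

## Bayesian estimation

The mediator and outcome equations have a priori independent parameters
and factoring likelihoods, so `gibbs_mediation()` runs one conjugate Gibbs
chain per equation: the full coefficient vector is drawn jointly from its
exact multivariate-normal conditional (removing within-equation
autocorrelation), then the residual variance from the inverse gamma with
shape `var_shape + n/2` and rate `var_inverse_scale + RSS/2`. The default
priors are diffuse: N(0, precision 10⁻³) on coefficients, IG(0.01, 0.01)
on variances. Effect-size draws apply the four formulas per iteration
with the standardizers fixed at the sample s_X, s_Y — matching the
frequentist estimator's standardizer; a per-draw model-implied
standardizer would define a slightly different estimand and is not used.

Defaults are 11,000 iterations with 1,000 burn-in and a single chain.
Conjugate Gibbs mixes essentially immediately for these small fixed-design
regressions, which is why one moderately long chain suffices; a
split-chain potential scale reduction factor is computed per path and
exposed (`$rhat`), and the simulation harness counts replications with any
PSRF above 1.1. The reference analyses used a general-purpose MCMC engine
whose sampler and chain length are unstated; conjugate Gibbs targets the
identical posterior, so only Monte Carlo error differs.

Posterior summaries are the mean, the median, the equal-tail interval
(same ceiling-rule order statistics as the percentile bootstrap), and the
HPD interval, computed as the narrowest contiguous window of
⌈level × n⌉ sorted draws, ties broken toward the lowest lower bound. By
construction the HPD is never wider than the equal-tail interval; the
test suite checks it against an exhaustive window search on small sets.

## The simulation harness and what it emulates

`generate_dataset()` and the study drivers simulate the stated generating
world: X standard normal (or Bernoulli(0.5) coded 0/1 — the balanced
allocation mirrors a randomized two-arm trial; the generating coding and
allocation are otherwise unstated), unit-variance normal residuals for
mediators and outcome, intercepts zero. Two-mediator residuals are
generated independently; the estimation side is agnostic to mediator
residual covariance (the outcome regression conditions on both mediators),
and whether the reference design correlated them is unstated, so zero
covariance was chosen once. Path values follow the stated grids: 0, 0.14,
0.39, 0.59 (single mediator; 5 sample sizes for the point study = 320
conditions, 4 for the interval study), and 0, 0.101, 0.314, 0.577 for the
mediated paths with c' in {0, 0.131, 0.4, 0.74}, constrained to a1 = b1
and a2 = b2 (= 256 conditions). The Bayesian study defaults to the listed
17 single-mediator and 21 two-mediator conditions at n = 50.

What a green harness run does **not** establish: anything about
non-normal residuals, unequal allocation, correlated mediator errors,
measurement error, or missing data — none of which the generator
emulates. The generator is a stated world, not a robustness sweep.

Metrics follow the usual definitions: bias (mean estimate − truth),
relative bias (bias/truth, undefined at truth 0, flagged above 0.05),
efficiency as the SD of estimates across replications, standardized bias
(bias/SD), power and Type I error as the proportion of intervals
excluding zero (the same predicate; the label depends only on whether the
true effect size is zero), coverage, mean width, and imbalance. Imbalance
is reported as P(truth above the interval) − P(truth below it), the sign
convention under which "all intervals sit above a zero truth" scores −1.
Type I error is classified against Bradley's liberal band [0.025, 0.075]
and coverage against [0.925, 0.975], bounds inclusive.

## Reproducibility and numerical choices

* One master seed drives everything; per-condition seeds are drawn from
  it by `sample.int`, so any condition is re-runnable in isolation.
  Within a condition, data generation and bootstrap index draws share one
  sequential RNG stream — simpler than per-replication substreams at the
  cost of not being able to replay a single replication alone.
* The study drivers use a vectorized closed-form OLS path (slopes from
  centered cross-products; the 2×2 and 3×3 normal equations solved by
  cofactors) instead of `lm()` per resample; equivalence with `lm()` is
  asserted in the tests to 1e-12. Designs are declared rank-deficient
  below an absolute pivot tolerance of 1e-10, appropriate for the O(1)
  scale of all simulated variables.
* Order-statistic indices apply `ceiling()` with a 1e-9 fuzz so that
  exact products like 0.025 × 1000 land on 25 rather than 26 through
  floating-point round-up.
* Degenerate inputs: constant X is a rank-deficiency error; c' = 0 makes
  the ratio an `NA`, never an error; intervals with too few defined draws
  return an undefined-interval signal (`NA` bounds) that downstream
  aggregation counts.

## Worked example

```{r example}
t3 <- worked_example("table3")
round(unlist(t3), 3)
```

From the published single-mediator coefficients (a = 0.549, b = 0.174,
c' = 0.234, s_Y = 1.217): the treatment raised the outcome by 0.078 SDs
through the mediator, 29% of the total effect was mediated, and the
indirect effect was 0.41 times the direct effect. Only these
printed-coefficient point estimates are reproducible — the original
n = 1315 trial dataset behind the published interval and posterior
columns is not public.

## Known limitations

* No latent-variable, multilevel, or missing-data mediation; no robust or
  sandwich standard errors; no BCa or studentized bootstrap.
* Variance-explained effect sizes (R², κ², "maximum possible mediation")
  are out of scope by design.
* Informative-prior elicitation is not supported; priors are the diffuse
  defaults unless overridden numerically.
* The proportion and ratio estimators are themselves unstable at small n
  and small effects — reproducing that instability (not fixing it) is the
  point of the harness.
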