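Package: medfx
Title: Effect-Size Measures for Single- and Two-Mediator Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Point and interval estimation of four effect-size measures for
    the indirect effect in single- and parallel two-mediator linear models:
    the partially standardized indirect effect (ab/sY), the fully
    standardized indirect effect (ab*sX/sY), the proportion mediated, and
    the ratio mediated. Provides ordinary least squares fitting with
    percentile and bias-corrected bootstrap confidence intervals, Bayesian
    estimation via conjugate Gibbs sampling with diffuse priors (posterior
    mean/median, equal-tail and highest posterior density credibility
    intervals), and a Monte Carlo harness that evaluates bias, relative
    bias, efficiency, power, Type I error rate, coverage, interval width and
    imbalance of the estimators, with Bradley robustness classification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
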