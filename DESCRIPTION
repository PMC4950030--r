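Package: hetvar
Title: Estimators and Confidence Intervals for the Between-Study Variance in
    Meta-Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Point estimators and confidence/credible intervals for the
    between-study variance (tau-squared) in random-effects meta-analysis.
    Implements the method-of-moments family (DerSimonian-Laird and its
    positive, two-step and bootstrap variants, Hedges-Olkin, Paule-Mandel,
    Hartung-Makambi, Hunter-Schmidt), likelihood-based estimators (ML, REML,
    approximate REML), the Sidik-Jonkman model-error-variance estimator, the
    Rukhin Bayes family, the Bayes modal estimator and a fully Bayesian
    estimator computed by deterministic quadrature.  Interval methods cover
    profile likelihood, Wald-type, Biggerstaff-Tweedie, Biggerstaff-Jackson
    and Jackson generalised-Q intervals (via the distribution of positive
    linear combinations of chi-squared variables), the Q-profile inversion,
    Sidik-Jonkman, parametric and non-parametric bootstrap intervals and
    Bayesian credible intervals.  A simulation harness evaluates bias, mean
    squared error and empirical coverage under the random-effects model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    metafor,
    optparse
Config/testthat/edition: 3
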