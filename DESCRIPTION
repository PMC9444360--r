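Package: lomaxshape
Title: Classical and Bayesian Estimation of the Lomax Shape Parameter
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimation of the shape parameter of the Lomax (Pareto type II)
    distribution when the scale parameter is known, as used for failure-time
    and biomedical duration data. Provides distribution primitives (density,
    distribution function, quantile, inverse-CDF sampling, sufficient
    statistic), five classical estimators (maximum likelihood, ordinary least
    squares and ridge regression on the linearized CDF, the uniformly minimum
    variance unbiased estimator, and a median-based estimator), and twelve
    Bayes point estimators arising from four gamma-conjugate priors (extended
    Jeffreys, chi-squared, inverted Levy, gamma) crossed with squared-error,
    LINEX, and composite-LINEX losses. Includes an analytic risk oracle that
    exploits the Gamma law of the sufficient statistic, and a Monte Carlo
    engine that compares all estimators by mean squared error over a
    configurable simulation design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
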