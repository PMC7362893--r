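Package: mlnmr
Title: Multilevel Network Meta-Regression with Mixed Individual and
    Aggregate Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Population-adjusted indirect comparisons and network
    meta-regression for connected networks of randomised trials where some
    studies provide individual patient data and others only aggregate
    summaries. The individual-level regression model is integrated over
    each aggregate study's joint covariate distribution (quasi-Monte-Carlo
    Sobol' points under a Gaussian copula with IPD-borrowed rank
    correlations) to form the aggregate-level likelihood, with a
    two-parameter binomial approximation to the Poisson-binomial for
    binary outcomes. Bayesian estimation via MCMC, goodness of fit by
    residual deviance and DIC, residual-heterogeneity and inconsistency
    checks, and population-average contrasts and absolute predictions in
    any target population.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    coda,
    igraph,
    jsonlite,
    rjags,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
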