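Package: prevatlas
Title: Model-Based Geostatistics for Small-Area Health Indicator Atlases
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for building subnational health and development indicator
    atlases from cluster-level household survey data. Simulates DHS-style
    geolocated cluster surveys (stratified sampling, confidentiality
    displacement, smooth gridded covariates, binomial outcomes from a
    logit-linked spatial Gaussian process), selects geospatial covariates by
    collinearity screening and backward-BIC search, fits a Bayesian
    point-referenced spatial binomial generalised linear model with an
    exponential covariance function by Markov chain Monte Carlo, predicts
    posterior mean and standard-deviation prevalence surfaces on a 5 km grid,
    cross-validates fits by k-fold resampling, and computes district-level
    rare-event and model-based estimates with Wilson, Byar, exact Poisson and
    delta-method confidence intervals, including a synthetic-cohort life-table
    child mortality rate.
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
    yaml
Config/testthat/edition: 3
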