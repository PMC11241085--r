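Package: speechCL
Title: Lower Confidence Limits for Maximum Speech Identification Scores
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates the one-tailed lower 95% confidence limit of the
    maximum speech identification score (PBmax) as a function of the
    pure-tone average (PTA) hearing threshold, as used in clinical
    audiometry to flag disproportionately poor word recognition. Three
    estimators are provided behind a single model-fitting interface: a
    censored-normal Monte-Carlo simulation applied to PTA sub-groups, the
    distribution-free Harrell-Davis quantile estimator with bootstrap
    standard errors, and nonlinear quantile regression of a three-parameter
    link curve by check-loss minimisation. Includes synthetic-cohort
    generation with analytically known conditional quantiles, a split-half
    accuracy and consistency harness, and a sub-grouping sensitivity
    analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
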