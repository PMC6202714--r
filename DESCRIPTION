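Package: eivpool
Title: Multilevel Models of Ellenberg Indicator Values for Vegetation
    Resurvey Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Infers environmental change from plant community resurvey data
    using Ellenberg-style indicator values. Species-level ordinal scores
    enter hierarchical Bayesian varying-intercept/varying-slope models
    (no pooling, partial pooling, and partial pooling with a habitat-level
    predictor) fitted by MCMC, yielding partially pooled plot mean scores
    and between-period changes with full posterior uncertainty. Provides
    level-specific Bayesian R-squared and Gelman-Pardoe pooling factors,
    DIC model comparison, a raw plot-mean mixed-model baseline with
    family-wise multiplicity correction, a species-depletion validation
    experiment for incomplete species lists, and a synthetic survey
    generator with ground truth for calibration testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    rjags,
    coda,
    lme4,
    mvtnorm,
    jsonlite,
    stats,
    utils
Suggests:
    multcomp,
    yaml,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
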