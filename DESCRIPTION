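Package: radcesium
Title: Time-Course Modelling of Radiocesium Burdens in Large Omnivorous Mammals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models the time course of total radiocesium (134Cs + 137Cs)
    activity concentrations in large omnivorous wild mammals (wild boar,
    Asian black bear) after a nuclear accident.  The burden model combines a
    two-isotope physical-decay environment term with an exponential (or
    power-law) ecological loss term and a sinusoidal seasonal oscillation.
    Estimation machinery includes multi-start nonlinear least squares with a
    closed-form linearised solution, robust M-regression (Huber/bisquare
    IRLS), nonlinear quantile (pinball-loss) regression with bootstrap
    standard errors, and mixed-effects fits with district/municipality random
    effects and per-district residual variances.  Derived summaries cover the
    ecological half-life ln(2)/mu, seasonal amplitude and phase, temporal
    train/test extrapolation scoring, and a weighted-regression AICc
    multimodel-inference analysis for zone/year summary data.  A synthetic
    data generator with known ground truth supports end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    nlme,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
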