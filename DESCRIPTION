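Package: coiltox
Title: Geometry-Based Prediction of E-Cigarette Carbonyl Emissions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts relative carbonyl toxin levels in e-cigarette aerosols
    from atomizer coil and wick geometry. Computes geometry-derived device
    scores (coil length / (wick surface area x wraps) and power-based
    alternatives), screens replicate emission measurements with a Grubbs
    outlier test, calibrates an exponential score-emission relationship by
    log-linear or nonlinear least squares, evaluates out-of-sample
    predictive accuracy with an identity-line coefficient of determination,
    and ranks candidate score models. Includes a synthetic device-fleet
    generator with multiplicative lognormal noise and high-side outliers so
    the whole pipeline is testable without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    graphics,
    utils,
    jsonlite,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
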