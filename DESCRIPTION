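Package: splitbeltfit
Title: Exponential Trend Models for Split-Belt Treadmill Symmetry Series
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Nonlinear regression toolkit for per-stride step length
    symmetry series from split-belt treadmill adaptation and
    de-adaptation experiments. Fits single and double exponential trend
    models by bounded particle swarm optimisation with penalty
    constraints followed by derivative-based local refinement, compares
    models with Akaike's information criterion, and reports
    common-language parameters (initial asymmetry, total change,
    strides to 50% change, final asymmetry, overshoot, residual
    standard deviation) with both linearized and exact
    (F-statistic profile) confidence intervals. Includes residual
    diagnostics and a seedable generator of synthetic symmetry series.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
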