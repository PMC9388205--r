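Package: countits
Title: Interrupted Time-Series Analysis of Weekly Health-Care Utilization Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for quasi-experimental interrupted time-series analysis of
    weekly event-count surveillance series, built around a transfer-function
    model: a dependent weekly count series is regressed on a contemporaneous
    control series and a coded intervention indicator, with residual
    autocorrelation absorbed by a subset autoregressive (optionally ARMA)
    noise model estimated by exact Gaussian maximum likelihood. Includes
    Friday-anchored weekly binning of encounter-level records, Box-Jenkins
    identification diagnostics (ACF/PACF, Ljung-Box), iterative detection and
    joint adjustment of additive outliers, temporary changes, and level
    shifts at a fixed t threshold, effect-size translation of intervention
    coefficients, a calibrated synthetic-data generator with full truth
    records for validation, and an end-to-end pipeline with sensitivity
    variants.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
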