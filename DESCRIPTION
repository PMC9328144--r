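Package: gutsred
Title: Reduced GUTS Survival Models for Time-Variable Exposure Risk Assessment
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Calibrates reduced General Unified Threshold models of Survival
    (GUTS-RED) in the stochastic-death and individual-tolerance variants to
    survival counts from aquatic toxicity tests, predicts median lethal
    profile multiplication factors (LPx) for time-variable exposure
    concentration profiles, and aggregates LP50 values across species into
    log-normal species sensitivity distributions with 5% hazard profile
    (HP5) endpoints. Includes readers for plain-text survival tables and
    exposure time series (including TOXSWA-style hourly output), the
    censoring and pooling rules used to prepare early-life-stage test data,
    a synthetic-data generator for toxicity tests and FOCUS-like exposure
    scenarios, and a study driver that runs the full
    calibration-prediction-ranking chain from one configuration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    lhs,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
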