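Package: pelower
Title: Counterfactual Modelling of First-Trimester Blood-Pressure Lowering
    and Pre-Eclampsia Risk
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Competing-risks modelling of pre-eclampsia from first-trimester
    screening data. A Gaussian survival-time model for the gestational age at
    delivery with pre-eclampsia is shifted by maternal characteristics and
    updated with biomarker multiples-of-median (mean arterial pressure,
    uterine artery pulsatility index, placental growth factor) to give
    personalised risks by gestational-age band. Counterfactual
    antihypertensive policies cap diastolic blood pressure at a target,
    simulate the accompanying systolic reduction, and re-score risk; expected
    incidences, relative and absolute risk reductions, and numbers needed to
    treat are aggregated into scenario tables. Includes calibration
    diagnostics (intercept and slope of a logistic recalibration) and a
    reproducible synthetic-cohort generator so the full pipeline is testable
    without access to confidential screening data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
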