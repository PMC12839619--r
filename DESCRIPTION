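Package: pbrtqc
Title: Patient-Based Real-Time Quality Control with a
    Transform-Truncate-Alarm Workflow
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for developing and evaluating patient-based real-time
    quality control (PBRTQC) schemes for clinical laboratory analytes.
    Implements a unified transform-truncate-alarm workflow: Box-Cox or log
    transformation of right-skewed patient-result streams, Winsorizing
    truncation against training-set quantile bounds, and moving average,
    moving quantile and exponentially weighted moving average control
    charts with consecutive-point alarm rules. Systematic analytical
    errors (stepwise bias and baseline-drift-plateau ramps) are simulated
    on bias-free streams, monitors are scored by sensitivity,
    false-positive rate, median number of patients before error detection
    (MNPed) and a composite ME_Score with a sigmoid delay penalty, and
    parameters are optimized by grid search with a two-stage,
    false-positive-averse selection rule and independent validation. A
    synthetic-data module generates log-normal analyte-like streams so
    the full pipeline can be exercised without access to laboratory
    information system extracts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ggplot2,
    parallel,
    stats,
    utils,
    withr,
    zoo
Suggests:
    MASS,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
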