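Package: copbalance
Title: Center-of-Pressure Stabilometry and Balance-Alteration Risk Modelling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying standing balance from center-of-pressure
    (CoP) sway recordings and for screening stabilometric indexes as markers
    of balance alteration in older adults. Computes the standard time-domain
    (distance, area, hybrid) and frequency-domain sway indexes from
    two-channel force-platform recordings, compares them between groups,
    selects an optimal diagnostic cut-off by Youden's statistic from ROC
    analysis (with DeLong confidence intervals), and fits an adjusted
    logistic risk model with Hosmer-Lemeshow calibration and Cochran
    sample-size planning. Includes a synthetic cohort and sway-trajectory
    generator so the full analysis can be exercised end to end without
    access to clinical data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    grDevices,
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    ggplot2,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
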