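Package: cmrqc
Title: Moving-Median Control Charts for Quantitative Cardiac MR Quality Assurance
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Patient-based statistical quality control for quantitative
    cardiovascular magnetic resonance (CMR) left-ventricular parameters.
    Ingests anonymized exam-report tables, applies per-parameter inclusion
    filters, and monitors trailing moving medians of EF, EDV, SV, LVM and
    derived quantities (ESV, BSA, BMI) against fixed tolerance intervals.
    Alerts (moving-median excursions beyond the limits) are detected,
    split into directed runs, and aggregated to per-year percentages.
    A synthetic phantom generator draws from a sex-stratified bimodal
    normal mixture and injects constant step biases, supporting
    Granger-causality attribution of drifts to candidate confounders,
    step-magnitude recovery from the moving-median curve, and Monte-Carlo
    estimation of average run length (ARL) and average delay time (ADT)
    as functions of window size and limit width.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    ggplot2
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    lmtest,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
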