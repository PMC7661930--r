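Package: tbipanel
Title: Threshold-Based Biomarker Panels and Partial-AUC Outcome Prediction in Traumatic Brain Injury
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Outcome-prognostication toolkit for CT-positive traumatic brain
    injury. Computes the Helsinki CT score from structured head-CT findings,
    builds empirical ROC curves with partial AUC restricted to a
    high-sensitivity band (90-100% sensitivity), selects constrained
    operating points, and constructs multi-marker threshold panels
    (per-marker cutoffs with a minimum-positive-rules decision cut) by
    exhaustive search under a sensitivity constraint. Includes Mann-Whitney
    group comparisons with exact small-sample enumeration, stratified
    bootstrap confidence intervals, a seeded synthetic cohort generator that
    emulates published summary statistics, and a command-line pipeline that
    emits the standard single-marker and panel report tables.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
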