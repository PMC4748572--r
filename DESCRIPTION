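Package: mewsr
Title: Modified Early Warning Score Pipeline for In-Hospital Cardiac
    Arrest Surveillance
Version: 0.1.0
Authors@R:
    person("Ward", "Analytics", email = "ward.analytics@example.org",
           role = c("aut", "cre"))
Description: Implements a hospital-customized Modified Early Warning
    Score (MEWS) track-and-trigger pipeline: a configurable vital-sign
    banding rubric with daily-maximum reduction, the warning-zone
    threshold audit (score-stratified in-hospital cardiac arrest rates
    with uncorrected chi-squared and exact hypergeometric tests),
    admission-denominated incidence analysis with monthly control
    limits and before/after comparison, an explicit callout-algorithm
    state machine with a cohort simulator, and a synthetic inpatient
    cohort generator calibrated to published score-stratified arrest
    rates so the whole pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
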