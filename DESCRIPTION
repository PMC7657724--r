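Package: eprowatch
Title: Electronic Patient-Reported Outcome Monitoring for Immune Checkpoint Inhibitor Therapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for weekly electronic patient-reported outcome (ePRO)
    symptom monitoring of cancer patients on anti-PD-(L)1 therapy. Implements
    an 18-symptom questionnaire with a declarative rule engine that maps
    patient-friendly answers to NCI-CTCAE v4.03 severity grades 0-4, an
    urgency algorithm that flags questionnaires for care-team review (any
    grade >= 3 symptom, or a jump from grade 0 to grade >= 2), an email
    prompt/reminder schedule with cohort compliance metrics, a longitudinal
    cohort simulator with treatment-benefit-linked symptom dynamics, and an
    analysis pipeline producing grade distributions, alert summaries, Pearson
    correlation heatmaps with effect-size classes, benefit-stratified symptom
    trajectories, and patient-experience survey summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
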