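Package: dialdep
Title: Depression Classification and Psychosocial Risk Modelling in Dialysis Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for cross-sectional psychiatric epidemiology in haemodialysis
    populations. Codes Clinical Interview Schedule-Revised (CIS-R) depression-section
    responses into ICD-10 depressive-episode diagnoses through a configurable rule
    table that supports item exclusions (appetite, weight, impairment) and a
    sensitivity mode imputing excluded items as present; scores PHQ-2 and HAMD-17
    screening instruments and quantifies screen-versus-diagnosis concordance;
    estimates prevalence with exact binomial intervals; runs block-wise backward
    stepwise logistic regression with a chi-squared/Fisher switching rule for
    contingency tables; and simulates synthetic dialysis cohorts with a latent
    depressive-severity process so the whole pipeline is testable without
    patient-level data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
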