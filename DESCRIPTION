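Package: comorbindex
Title: Claims-Based Cancer Comorbidity Index and Actual-Prognosis Tables
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds a claims-based comorbidity index for cancer patients from
    linked registry, insurance-claims and cause-of-death tables, and reports
    actual prognosis (absolute probabilities of dying from cancer, dying from
    other causes, and surviving) under competing risks. Ascertains 18 comorbid
    conditions from diagnosis codes using lookback windows with a six-month
    washout, fits Cox proportional-hazards models by Efron partial likelihood
    with an iterative negative-coefficient-deletion step to obtain nonnegative
    index weights, assigns three comorbidity levels with a severe-illness
    override, validates discrimination with incident/dynamic time-dependent
    AUC on deterministic nested train/validation/test splits, and estimates
    cause-specific cumulative incidence with the Aalen-Johansen estimator.
    Includes a synthetic-cohort generator emulating the three-way linkage so
    the whole pipeline is testable without restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    survival,
    cmprsk,
    jsonlite,
    optparse
Config/testthat/edition: 3
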