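Package: akicds
Title: Electronic Clinical Decision Support for Hospital-Acquired Acute
    Kidney Injury
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A testable engine for creatinine-based detection and KDIGO
    staging of hospital-acquired acute kidney injury (AKI), with an
    NHS-England-style baseline-creatinine selection rule, a per-patient
    alert lifecycle state machine (first alert, progression, recovery,
    re-alert, acknowledgment), formulary-driven nephrotoxic-medication
    order warnings, a clinical-summary dashboard aggregator,
    volume-status-branched order-set recommendations, a silent-mode
    cohort evaluator producing audit frequency tables, and a seeded
    synthetic-cohort generator so every component is exercisable on
    planted patient event streams with no external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
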