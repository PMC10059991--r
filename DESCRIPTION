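Package: gefed
Title: Federated Grammatical Evolution for Interpretable Glucose
    Forecasting
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Evolves interpretable arithmetic models that forecast the
    glycemic band of a type-1-diabetes patient 30 minutes ahead from
    continuous glucose monitoring (CGM) readings, insulin dosing and meal
    carbohydrates.  Per-patient models are fitted by Grammatical
    Evolution over a constrained expression grammar, with fitness equal
    to the class-frequency-weighted F1 score over seven clinical
    glycemic bands.  A master/slave federated orchestrator (FLEA)
    periodically migrates each patient's best model to the other
    patients, exchanging models but never raw data, and selects a global
    model by cross-evaluation.  Includes Hovorka-type insulin and
    carbohydrate absorption preprocessing, an Ohio-style CGM XML reader,
    a synthetic cohort generator, and the Quade test with five post-hoc
    procedures for comparing algorithms across subjects.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    jsonlite,
    stats,
    utils,
    xml2
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
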