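Package: costas
Title: Clinically Oriented Scoring for Intra-Arterial Spasmolysis Triage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements the COSTAS clinical score for selecting aneurysmal
    subarachnoid-hemorrhage patients with symptomatic cerebral vasospasm for
    intra-arterial spasmolysis. Provides nine threshold-band parameter scorers
    aggregating to a 0-18 total, screening rules for suspected vasospasm
    (transcranial Doppler velocity criteria) and delayed cerebral ischemia
    (Glasgow Coma Scale deterioration criteria), a noradrenaline infusion and
    dose-conversion calculator with literature shock-severity bands, a support
    vector machine vasospasm-risk predictor with holdout and cross-validation
    evaluation, and a synthetic SAH cohort generator for testing and training.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    kernlab,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
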