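Package: scarscreen
Title: In Silico Screening of Prognostic Biomarkers of Pathological
    Scarring in Skin Wounds
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulates virtual cohorts of wound-healing trajectories from a
    kinetic rate-equation model under random parameter perturbation,
    classifies each simulated wound's scarring outcome from day-40 collagen
    and fibroblast fold changes, screens wound proteins as diagnostic and
    prognostic biomarker candidates by the Bhattacharyya overlap of their
    concentration distributions, and quantifies prognostic accuracy with
    logistic-regression marker panels, ROC/AUC with DeLong variance
    estimates and paired tests, and stratified tenfold cross-validation.
    Ships a calibrated twelve-state reference model of injury-initiated
    wound healing and a plug-in contract for user-supplied kinetic models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    ggplot2,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
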