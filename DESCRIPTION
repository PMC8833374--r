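Package: stpscore
Title: Signal Transduction Pathway Activity Scoring in CD4+ T Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Calibrate-then-freeze Bayesian-network scoring of signal
    transduction pathway (STP) activity from transcription-factor
    target-gene expression, reported as log2 odds of pathway activity.
    Includes the surrounding workflow needed to classify CD4+ T-cell
    functional state: per-sample Affymetrix-style quality control as a
    configurable rule engine, normal-range (mean + 2SD) thresholding of
    healthy-reference scores, exact small-sample nonparametric group
    comparisons, matching of sample pathway-activity profiles to
    reference immune cell subsets (resting, activated, Th1, Th2, Treg,
    iTreg), and a synthetic-cohort generator with planted per-pathway
    activation ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
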