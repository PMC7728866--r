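Package: prolink
Title: IRT Linking of Single-Item Symptom Measures to the PROMIS T-Score Metric
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Places single-item patient-reported outcome measures (0-10
    numeric rating scales and 1-5 PRO-CTCAE items) on the PROMIS T-score
    metric using item response theory. Implements graded-response-model
    calibration by marginal maximum likelihood (free, fixed-anchor and
    concurrent variants), Stocking-Lord test-characteristic-curve linking,
    raw-score-to-T-score crosswalk tables via the Lord-Wingersky recursion
    with summed-score EAP, and the standard linking-assumption screens
    (inter-measure correlations, subgroup standardized-mean-difference
    invariance, and omega-hierarchical unidimensionality from polychoric
    correlations with a Schmid-Leiman transformation). Ships a calibrated
    item-parameter bank for five NRS and fifteen PRO-CTCAE cancer symptom
    items together with the published concordance tables, and a synthetic
    single-group cohort generator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, tools, graphics
Suggests: testthat (>= 3.0.0), mvtnorm, jsonlite, yaml, withr, Matrix
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
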