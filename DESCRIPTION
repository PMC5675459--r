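Package: pairscreen
Title: Predicting High-Order Drug Cocktail Effects from Single-Dose Pair
    Measurements
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Analysis of fully factorial drug-combination viability screens
    measured at a single dose. Implements a family of cocktail-effect
    predictors built from single-drug and drug-pair viabilities -- Bliss
    independence, log-linear regression, the Isserlis maximum-entropy
    formula, and the pairs model, which predicts an M-drug cocktail as the
    product of its pair viabilities raised to the power 1/(M-1) -- together
    with Bliss-based interaction scoring with percentile-bootstrap
    confidence intervals, synergy/antagonism classification,
    pair-consistency analysis, model benchmarking (R-squared, alpha scans
    over the log-linear family, top-k ranking accuracy), analytic and
    Monte-Carlo noise-amplification factors, and a synthetic-screen
    generator with known ground truth. A six-drug, two-cell-line
    chemotherapy screen is shipped as a built-in dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
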