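Package: clustsens
Title: Clustered Matched-Pair Diagnostic Accuracy Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Sensitivity estimation and method comparison for paired
    diagnostic tests evaluated against a reference standard on clustered
    binary data, as arises when several lesion sites are scored within each
    patient. Provides exact (Clopper-Pearson) and score (Wilson) intervals
    for unclustered proportions, a ratio-of-totals estimator with a
    cluster-robust (sandwich) variance for lesion-level sensitivity,
    classical and cluster-adjusted McNemar tests of marginal homogeneity,
    a non-inferiority test for the sensitivity difference of two tests with
    a configurable margin, a synthetic cohort generator with beta-distributed
    patient effects and Gaussian-copula paired detections, and Monte-Carlo
    power/type-I-error studies.
License: MIT
Encoding: UTF-8
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
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
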