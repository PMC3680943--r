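Package: vasculotype
Title: Class Discovery and Subtype-Adjusted Outcome Prediction for Tumor Vasculature Expression Profiles
Version: 0.1.0
Authors@R:
    person("Vasculotype", "Developers", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for the analysis of microdissected tumor-vasculature
    gene-expression cohorts: probe collapsing and variance filtering,
    unsupervised class discovery by Ward clustering on correlation
    distances with bootstrap clade support, empirical-Bayes moderated
    t-statistics for two-group differential expression with
    Benjamini-Hochberg FDR control, pericyte-marker scoring and
    gene-signature overlap testing, and a subtype-adjusted nested
    leave-one-out cross-validated linear-discriminant predictor of
    recurrence. Includes a synthetic-cohort generator with planted
    tumor, subtype, and recurrence effects so every stage of the
    pipeline can be exercised and validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    matrixStats
Suggests:
    testthat (>= 3.0.0),
    limma,
    withr,
    ape
Config/testthat/edition: 3
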