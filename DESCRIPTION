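Package: nlsig
Title: Normal-Like Tumor Subgroup Discovery and Minimal Gene Expression
    Signatures from Bulk RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Discovers a small "normal-like" tumor subgroup in bulk RNA-seq
    cohorts by hierarchical clustering of differentially expressed genes on
    Pearson correlation distance, anchored on normal control tissues, and
    searches exhaustively for minimal k-gene classifier signatures (k = 1-3)
    that separate the normal-like group from other tumors using random-forest
    impurity ranking, a k-nearest-neighbor classifier and stratified
    cross-validation. Includes a negative-binomial two-group differential
    expression test with Benjamini-Hochberg correction, Kaplan-Meier /
    log-rank / Cox proportional-hazards survival statistics, exact Fisher
    tests for r x c contingency tables (enumeration and Monte-Carlo), and a
    synthetic cohort generator with planted subgroup structure, signature
    genes and exponential survival for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    ranger,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
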