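Package: kappool
Title: Severity-Weighted Kappa with Pooling over Observation Periods
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Estimates inter-rater reliability of ordinal ratings (the
    five-category Quality of Interactions Schedule, or any k-category
    ordinal scale) using weighted Cohen's kappa with agreement-weight
    matrices that grade the severity of misclassification, including the
    QuIS-specific schemes A1-A6, B1-B3 and C1-C3 alongside identity,
    linear and quadratic weights.  Per-observation-period estimates with
    Fleiss standard errors are combined into a single summary by
    collapsing, inverse-variance fixed-effects pooling, DerSimonian-Laird
    random-effects pooling, or simple averaging, with a chi-square test
    for heterogeneity.  Includes a simulator for inter-rater studies with
    analytically known true weighted kappa and between-period
    heterogeneity, readers and writers for paired-rating CSV files, and
    report/forest-data export.
License: MIT + file LICENSE
Encoding: UTF-8
Imports: jsonlite, stats, utils
Suggests: testthat (>= 3.0.0), metafor, withr, yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
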