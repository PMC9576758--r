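Package: phenocopyr
Title: Phenocopy Gene-Expression Signatures for Targeted-Therapy Response
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trains expression-based classifiers of driver-gene mutation status
    ("phenocopy signatures") with gradient-boosted trees and a hinge loss, and
    quantifies whether their predictions add to DNA mutation status in explaining
    targeted-therapy response. Provides mutation filtering and a pathogenicity
    consensus over SIFT, PolyPhen-2, FATHMM and ClinVar annotations, cross-platform
    rank normalization of expression matrices, nested ordinary-least-squares models
    compared by likelihood-ratio chi-square tests with Benjamini-Hochberg FDR
    control, clinical-biomarker metrics (sensitivity, specificity, PPV, NPV) over
    mutation/phenocopy strata, group rate comparisons for CNV enrichment and paired
    pre/post-treatment cohorts, and a synthetic-cohort generator encoding the causal
    structure the analysis assumes so every stage is testable against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
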