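Package: rvis
Title: Residual Variation Intolerance Scoring for Exome Variant Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computes gene-level intolerance to functional genetic
    variation from cohort-scale exome variant tables. Each gene's count
    of common functional variants (missense, nonsense, splice) is
    regressed on its total count of protein-coding variants, and the
    studentized residual is the Residual Variation Intolerance Score
    (RVIS): genes with less common functional variation than expected
    for their mutational burden score negative and rank as intolerant.
    Includes consolidated transcript footprints with coverage masking,
    variant filtering and classification (with a PolyPhen-2-informed
    mode), percentile ranking, gene-list evaluation (logistic
    association, DeLong AUC, Mann-Whitney U), de novo mutation
    prioritization in a two-dimensional gene-score by variant-score
    "hot zone", and a synthetic exome/trio simulator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    IRanges,
    pROC,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
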