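Package: proteorank
Title: Cross-Tissue Integration and Rank Aggregation of Quantitative
    Proteome Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for integrating differential-expression evidence across
    multiple tandem-mass-tag (TMT) proteome cohorts of brain cortex,
    cerebrospinal fluid and serum. Provides per-dataset moderated-t
    differential expression with blood-contamination residualization and
    Z-scored fold changes, abundance-depth detectability analysis,
    cross-dataset overlap and direction-pattern classification, tiered
    rank aggregation by uniform order statistics with a
    permutation-calibrated null, and preranked set-permutation
    enrichment. A synthetic multi-cohort study generator with planted
    ground truth makes every stage testable without access to restricted
    cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    Rcpp,
    stats,
    tibble,
    tidyr,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    limma,
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
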