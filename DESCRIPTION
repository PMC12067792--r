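Package: hiercdm
Title: Statistical Validation of Attribute Hierarchies in Cognitive
    Diagnosis Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits saturated and hierarchy-restricted cognitive diagnosis
    models (identity-link G-DINA and the hierarchical diagnostic
    classification model) by marginal maximum likelihood EM, computes
    empirical cross-product (XPD) and observed (Obs) information matrices
    for the free parameters, and tests a prespecified attribute hierarchy
    with constraint-matrix Wald statistics and the likelihood-ratio test.
    Includes a data generator for hierarchy-constrained attribute
    patterns, Q-matrices and binary item responses, and a replication
    harness for empirical Type I error and power studies of the tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    MASS,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    yaml,
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
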