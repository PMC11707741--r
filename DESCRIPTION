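Package: pharmforge
Title: Curation and Analysis of Drug Product Composition and Oral Absorption Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for building and analysing a relational database of drug
    products from semistructured product-information documents. Covers
    regex-based section extraction from SmPC-style texts, controlled-vocabulary
    normalisation of excipients, dosage forms and routes, salt and solvate
    standardisation of active-substance structures down to the parent molecule,
    drug-likeness evaluation against named descriptor rulesets, apriori
    association-rule mining of excipient compositions, a Mann-Whitney screen of
    descriptor/excipient associations, and binary classification of the human
    oral fraction absorbed with modelability assessment. Ships a synthetic
    corpus generator with retained ground truth so the full pipeline is
    testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineOB,
    ChemmineR,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    ranger,
    readr,
    rlang,
    rpart,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    xgboost
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
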