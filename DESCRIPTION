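Package: epmotifs
Title: Motif Pairs that Co-Occur in Interacting Enhancer-Promoter Pairs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies pairs of transcription-factor binding motifs, one
    bound in enhancers and one in promoters, that significantly co-occur in
    physically interacting enhancer-promoter (EP) pairs. Builds positive and
    negative EP pairs from a binned, normalized chromatin-contact matrix and
    activity-flagged annotations; scans sequences with position weight
    matrices using exact score-distribution p-values; enumerates co-occurring
    motif modules (Apriori-style) and scores oriented enhancer/promoter motif
    pairs with a Poisson-clumping tail and multiple-testing correction; tests
    homogeneous motif pairs and enhancer/promoter preference with binomial
    tails and protein-interaction enrichment with a hypergeometric tail; and
    evaluates how well discovered motif pairs separate interacting from
    non-interacting EP pairs with L1-penalized logistic regression under
    stratified 10-fold cross-validation. A synthetic-data generator emulates
    all inputs with planted motif-pair signal for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
LinkingTo:
    Rcpp
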