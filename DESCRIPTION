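Package: tumorsig
Title: Tumor-Type Signatures from Somatic Mutation Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A pipeline for classifying tumor samples into cancer types from
    their sets of somatically mutated genes. Each sample is encoded three ways:
    gene-set enrichment scores (the -log10 upper-tail hypergeometric
    probability of overlap with GO-like and KEGG-like gene sets), skip-gram
    embeddings of per-sample gene "sentences", and embeddings of biased random
    walks over a weighted gene-interaction network. Features are screened with
    a shadow-feature (Boruta-style) filter, ranked by four complementary
    methods (L1-penalized regression, minimum-redundancy-maximum-relevance,
    Monte Carlo feature selection, and gradient-boosted tree split counts),
    and evaluated by incremental feature selection under SMOTE-balanced
    stratified cross-validation with weighted F1 as the objective. Decision
    tree rules are extracted for interpretation, and a synthetic-cohort
    generator with planted class-specific driver pathways supports end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    glmnet,
    igraph,
    jsonlite,
    Matrix,
    purrr,
    ranger,
    Rcpp,
    readr,
    rlang,
    rpart,
    stats,
    tibble,
    tidyr,
    utils,
    xgboost
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
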