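Package: radiogat
Title: Radiogenomic Graph Attention Fusion for Lymph Node Metastasis Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Pipeline for predicting lymph node metastasis from paired gene
    expression and PET/CT radiomic features. Discovers co-expression modules
    with a weighted correlation network (soft-threshold adjacency, topological
    overlap, hierarchical module detection, module eigengenes and gene
    significance), filters metastasis-associated genes through differential
    expression, hypergeometric pathway over-representation, univariate
    logistic screening and gene-significance ranking, builds attributed
    protein-protein interaction graphs from STRING-style edge lists, screens
    radiomic features by ROC AUC with Hanley-McNeil standard errors, and fits
    a multi-head graph-attention fusion classifier combining per-module graph
    embeddings with fully-connected image features. Includes SMOTE class
    balancing, stratified repeated cross-validation with confidence
    intervals, and a synthetic-cohort generator that emulates the assumed
    data structure so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    mclust,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
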