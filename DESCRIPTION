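Package: causalembed
Title: Signed Cause-Effect Embeddings of Genes, Functions and Drugs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Unsupervised embeddings of genes (and drugs) from literature-style
    signed causal gene expression relationships, using three strategies: a
    spectral truncated-SVD factorization of the row-normalized signed
    bi-adjacency matrix, a nonlinear autoencoder with a ReLU hidden layer, and
    a signed coregulation-graph approach that encodes edge signs by node
    replication and embeds random walks with skip-gram. Function and disease
    embeddings are obtained by per-function linear regression in the same
    space, yielding signed gene-function scores, z-scores, and a cosine
    similarity significance threshold. Includes balanced-masking
    cross-validation (ROC/PRC, AUC, precision at low recall), construction of
    disease-centric bipartite gene-function networks, a drug-disease MLP
    predictor, and a synthetic-data generator with planted low-rank structure
    so the full pipeline is testable without proprietary content.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
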