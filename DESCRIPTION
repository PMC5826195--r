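Package: grmda
Title: Graph Regression for miRNA-Disease Association Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Scores candidate microRNA-disease associations by graph
    regression between low-rank latent projections of the known association
    network and two similarity networks. Disease similarity integrates two
    ontology-DAG semantic models with a Gaussian interaction-profile kernel
    fallback; miRNA similarity integrates a precomputed functional similarity
    matrix with the analogous kernel. Latent spaces are obtained by truncated
    singular value decomposition and linked by partial least squares
    regression. Includes leave-one-out and repeated k-fold cross-validation
    with global-rank ROC/AUC, per-disease ranking with a new-disease mode,
    plain-text readers and writers for all inputs, and a seeded synthetic-data
    generator (planted low-rank bipartite graph, random disease DAG forest,
    noisy functional similarity) so the full pipeline is testable without
    external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite,
    mixOmics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
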