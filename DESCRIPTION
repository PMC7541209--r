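Package: netpharm
Title: Network Pharmacology Analysis of Protein-Protein Interaction Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for network-pharmacology analysis of scored
    protein-protein interaction networks (PPINs). From a STRING-style scored
    edge list and a target-protein list it builds a true PPIN and a contrast
    ("false") PPIN of non-interacting target-incident pairs, computes
    link-prediction edge scores (Jaccard, preferential attachment, common
    neighbors, resource allocation) and node centralities (degree, closeness,
    eigenvector, betweenness, local clustering, eccentricity), selects
    discriminating attributes by two-sample tests and classifier importance,
    prunes the network by percentile thresholds, identifies protein clusters
    with a from-scratch Markov Cluster (MCL) algorithm, and performs
    hypergeometric pathway overrepresentation analysis with cross-cluster
    overlap reporting. A fully seeded synthetic-data module generates
    planted-community interaction networks and pathway gene sets so the whole
    pipeline is testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    Matrix,
    glmnet,
    randomForest,
    pROC,
    jsonlite,
    yaml,
    withr,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
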