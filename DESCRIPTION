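Package: toxsig
Title: Toxicogenomic Gene Signature Prioritization from Consensus
    Co-Expression Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Derives ranked, reduced gene signatures from multi-dataset
    toxicogenomic expression data. Builds per-dataset Pearson co-expression
    networks and intersects them into a consensus network, re-weights edges
    with per-gene prior-knowledge scores encoding pathway membership and
    interaction-graph centrality, partitions the network with a Markov
    Cluster Algorithm, and selects genes cluster-by-cluster with random
    forests under an accuracy-proportional quota. Includes a seeded
    synthetic-data generator for planted co-expression modules and
    dose-response curves, a cross-validated classifier panel with
    confusion-matrix metrics and random-gene-set baselines, and a
    transcriptomic benchmark-dose (BMD) pipeline with multi-model curve
    fitting, AIC selection and pathway-level aggregation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    SummarizedExperiment,
    S4Vectors,
    igraph,
    randomForest,
    MASS,
    e1071,
    rpart,
    class,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
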