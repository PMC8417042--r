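Package: mhrwr
Title: Random Walk with Restart on Multiplex and Heterogeneous
    Networks for lncRNA-Disease Association Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Ranks candidate lncRNA-disease associations by a random walk
    with restart on a multiplex and heterogeneous network. Multiple
    lncRNA similarity layers (functional similarity from shared disease
    annotations, Gaussian interaction profile kernel) and multiple
    disease similarity layers (ontology semantic similarity, Gaussian
    interaction profile kernel) are coupled through a replicated
    bipartite association matrix into a single row-stochastic transition
    matrix; the stationary restart distribution scores candidates.
    Includes leave-one-out cross-validation with ROC/AUC and PR/AUPR,
    a seeded synthetic benchmark generator with planted co-cluster
    structure, TSV/OBO readers, and a command-line entry point.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite,
    optparse,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
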