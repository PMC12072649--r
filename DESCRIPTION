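Package: GraphDTI
Title: Network Topology Fusion and Uncertainty-Aware Drug-Target
    Interaction Screening for Disease Gene Networks
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for network-based drug repurposing on disease gene
    interaction networks. Computes ten topological centrality metrics and
    fuses them into a weighted Functional Centrality Index (FCI), detects
    communities by recursive leading-eigenvector modularity optimization,
    and scores drug-gene interactions with a multi-modal attention network
    combining molecular fingerprints, physicochemical descriptors, and
    cluster-aware gene embeddings. Predictions carry dual uncertainty
    estimates (an aleatoric head plus Monte Carlo dropout), which drive
    library-scale screening, uncertainty filtering, ranking, and
    multi-target (polypharmacology) candidate extraction. A synthetic-data
    generator with planted community structure and planted multi-target
    drugs supports end-to-end benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    igraph,
    methods,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    ChemmineOB,
    pROC,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
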