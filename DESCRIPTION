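Package: modnet
Title: Network-Based Prioritization of Phenotype-Modifier Genes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A reusable pipeline for prioritizing candidate phenotype-modifier
    genes of a monogenic disease from public systems-biology resources.
    Implements ontology-driven gene-set selection (GO biological process and
    Human Phenotype Ontology annotations), protein-protein interaction network
    statistics with forward and reverse genetics candidate selection
    (betweenness, closeness, HITS hub/authority), a differential-expression
    stage with phenotype-aware network propagation and active-subnetwork
    search, random-walk-with-restart ranking of candidates against a phenotype
    node on a heterogeneous gene-phenotype network, and summaries of variant
    classification count tables. Ships a synthetic-data generator with known
    ground truth so every stage is testable without external databases.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    limma,
    Matrix,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
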