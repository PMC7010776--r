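Package: flowCentral
Title: Flow Centrality Analysis of Disease Module Cross-Talk in Protein
    Interaction Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies genes mediating the interaction between two disease
    modules on a protein-protein interaction network. Implements flow
    centrality, a module-to-module betweenness measure over the shortest
    paths connecting a source and a target gene set, and its significance
    score against a degree-preserved null of randomized, re-expanded
    modules. Includes DIAMOnD connectivity-significance module expansion
    with enrichment-based sizing, selection of flow-central network paths,
    length- and endpoint-preserved null path ensembles, sequential Resnik
    best-match-average ontology similarity along paths, sequential
    coexpression with multi-probe gene handling, the supporting rank
    statistics, and seeded synthetic generators (planted-bridge graphs,
    annotation corpora, latent-factor expression) for validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    igraph,
    jsonlite,
    Rcpp,
    S4Vectors,
    SummarizedExperiment
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
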