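Package: netpharm
Title: Network Pharmacology Inference with Drug-Disease Proximity and
    Random Walk with Restart
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for interactome-based evaluation of multi-compound
    interventions against disease gene modules. Implements ADME-style
    compound screening (oral bioavailability and drug-likeness cut-offs),
    closest-distance network proximity between a drug-target set and a
    disease-gene set standardized against a size- and degree-matched
    random null, random-walk-with-restart prioritization of hub genes in
    drug-disease subnetworks, greedy modularity community detection,
    hypergeometric over-representation analysis against GMT term
    collections, and a synthetic-data generator that plants recoverable
    ground truth for every stage. A single orchestrator runs the whole
    chain reproducibly from one configuration.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    igraph,
    Matrix,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
biocViews: NetworkInference, GraphAndNetwork, SystemsBiology, Pathways,
    GeneSetEnrichment
RoxygenNote: 7.3.3
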