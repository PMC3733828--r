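Package: mirhyper
Title: Hypergraph-Based Discovery of Higher-Order miRNA-mRNA Modules
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Learns a hypergraph-based classifier of cancer stages from
    matched miRNA and mRNA expression profiles.  Each hyperedge groups a
    small set of miRNAs and mRNAs and carries per-stage Gaussian statistics
    and per-stage weights; the model is trained by iterating an evolutionary
    structure-learning phase (mutual-information-guided hyperedge sampling
    with multivariate-mutual-information-based initial weights and a decaying
    replacement schedule) with a gradient-descent weight-refinement phase.
    Learned models are converted into stage-specific weighted interaction
    networks with up/down regulation annotation.  Includes synthetic-data
    generators, a cross-validation harness with a k-nearest-neighbour
    baseline, stability and module-recovery statistics, and JSON model
    serialization.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, jsonlite, igraph
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
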