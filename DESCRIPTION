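Package: sibsam
Title: Simulation-Based Inference for Bulk Segregant Analysis QTL Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Forward-in-time simulators for bulk segregant analysis (BSA)
    and introgression mapping (IM) experiments in Drosophila-like genomes,
    together with a simulation-based inference pipeline (SIBSAM) for QTL
    mapping from pooled-sequencing ancestry-difference profiles. The
    pipeline identifies primary and secondary peaks on smoothed genome
    scans, assigns significance by comparison with no-QTL null
    simulations, and estimates QTL strengths and genomic confidence
    intervals by approximate Bayesian rejection sampling against single-QTL
    and linked-QTL-cluster simulations. Also includes an experimental
    design evaluation harness for comparing BSA and IM localization
    accuracy across breeding designs.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
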