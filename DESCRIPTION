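Package: mircand
Title: SVM-Based Prediction of Probable miRNA Coding Regions in Genome-Scale Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Scans nucleotide sequences for stem-loop (hairpin) structures,
    enumerates every possible mature-miRNA placement inside each hairpin,
    scores placements with structural, sequence-composition and stability
    features of the (ppri-miRNA, pre-miRNA, miRNA) triple, classifies them
    with a taxon-specific RBF support vector machine, and consolidates
    overlapping positive placements into most probable miRNA coding regions.
    Includes corpus construction with random-start decoy negatives, empirical
    range filtering, greedy beam-search feature-chain selection, a synthetic
    hairpin/genome simulator for fully self-contained training and testing,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    e1071,
    jsonlite,
    yaml,
    Rcpp,
    stats,
    utils,
    methods,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
SystemRequirements: ViennaRNA (RNAfold) for the default external folding backend
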