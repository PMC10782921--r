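Package: rein
Title: Silencer Prediction on Regulatory Element Interaction Networks
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Builds regulatory element interaction networks (REINs) from
    ChIA-PET-style chromatin loops, in which merged loop anchors are nodes
    and loops are edges. Anchor nodes are annotated with cis-regulatory
    element classes (silencer, non-silencer, enhancer, promoter), featurized
    with one-hot DNA sequence plus per-base histone-modification and
    transcription-factor binding signal, and classified as silencers or
    non-silencers by a hybrid neural model that combines a convolutional
    branch over the linear features with a GraphSAGE branch over the
    network. Includes evaluation machinery (confusion metrics, AUROC/AUPR,
    repeated stratified cross-validation, Davies-Bouldin separation index,
    motif enrichment scores, aggregate peak analysis) and a synthetic
    fixture generator with planted class structure for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    igraph,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Epigenetics, GenePrediction, Network, Classification
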