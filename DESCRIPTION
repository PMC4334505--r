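Package: Rnt1Scan
Title: Genome-Wide Detection of Yeast RNase III (Rnt1p) Cleavage Signals
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for mapping the stem-loop cleavage signals of the
    Saccharomyces cerevisiae double-stranded-RNA ribonuclease Rnt1p.
    Implements three complementary detection strategies: an in silico
    scanner that enumerates NGNN-tetraloop (G2-loop) stem-loops genome-wide
    and scores them with a trainable sequence/structure/similarity model; a
    tiling-array pipeline with hybridization-energy probe correction, four
    normalization variants, exact piecewise-constant changepoint
    segmentation with BIC model selection, and callers for overexpressed
    (expression array) and cleaved (Cut and Chip) regions; and a
    sequencing-based cleavage-fragment pipeline (SALI) covering adapter
    trimming, unique exact mapping, identical-read cluster enrichment and
    overlap merging. A minimum-free-energy folding engine with wobble and
    A-C pairs classifies terminal loops, positional Fisher/chi-squared
    statistics derive substrate consensus models, and an evaluation layer
    compares methods against known substrates and qPCR. A seeded
    synthetic-data generator with ground-truth manifests drives recovery
    testing of every pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    SummarizedExperiment,
    rtracklayer,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: Transcriptomics, GenePrediction, Sequencing, Microarray,
    StructuralPrediction
RoxygenNote: 7.3.3
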