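Package: mtagmap
Title: Single-Molecule Analysis of Methyltransferase-Directed DNA Labeling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis of optical DNA mapping experiments in
    which DNA methyltransferases deposit fluorophores at short recognition
    motifs. Builds reference motif maps from sequences (with in-silico PCR),
    simulates labeled and stretched molecules, two-channel plasmid fields and
    single-step photobleaching movies with ground truth, performs
    bleaching-assisted fluorophore localization and per-plasmid label
    counting, aligns per-molecule label positions to reference maps with a
    stretch-tolerant dynamic program, builds consensus maps with dual-strand
    label removal, and quantifies off-target labeling, labeling kinetics and
    non-specific binding.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    EBImage,
    tiff,
    yaml,
    jsonlite,
    minpack.lm,
    Rcpp,
    methods,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
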