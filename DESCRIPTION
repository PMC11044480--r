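Package: mobilomeR
Title: Detection of Active LTR Retrotransposons from Nanopore eccDNA and
    Whole-Genome Long Reads
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An analysis pipeline for plant mobilome studies based on long-read
    sequencing of extrachromosomal circular DNA (eccDNA). Maps noisy long reads
    with a built-in seed-chain-extend aligner, counts eccDNA reads per annotated
    LTR retrotransposon and calls differential activity between a treated and a
    control condition with Fisher's exact test, decomposes rolling-circle
    concatemer reads into monomers to classify eccDNA structure (solo-LTR,
    full-length with one or two LTRs, truncated), quantifies divergence of
    eccDNA consensus sequences from the reference and assigns the
    species-of-origin of active elements against a panel of relative genomes.
    A companion whole-genome module computes SNP-density tracks, segments
    interspecific introgressions and calls non-reference transposon insertions
    with target-site duplications. A synthetic-data generator emulates every
    input at desk scale with machine-readable ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    ape,
    jsonlite,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
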