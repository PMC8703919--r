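Package: alloplasmy
Title: Donor-Segment Attribution and CMS Typing in Alloplasmic Organelle Genomes
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Comparative mitogenomics toolkit for alloplasmic cytoplasmic male
    sterile (CMS) lines. Finds exact-match anchors and syntenic blocks between
    a hybrid (cybrid) mitochondrial genome and its recipient and donor parents,
    attributes every hybrid position to an origin class, extracts the
    donor-derived "alien cytoplasm" regions with summary statistics, annotates
    synonymous and amino-acid-changing differences between orthologous coding
    sequences, designs region-diagnostic PCR markers and screens genomes by
    in-silico PCR, and types CMS sterility ORFs (orf138/orf125/orf112) by the
    tandem copy number of their 39-nt repeat unit. Ships a synthetic trio
    generator with exactly known ground truth so the whole pipeline is testable
    without external assemblies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    BiocGenerics,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    rtracklayer,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Genetics, ComparativeGenomics, SequenceMatching, Alignment
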