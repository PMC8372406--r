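Package: plastomics
Title: Comparative Plastome Structure, Repeats, Marker Screening and
    Phylogenetic Informativeness
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for comparative analysis of annotated chloroplast genomes
    (plastomes): detection of the quadripartite structure (LSC/SSC and the two
    inverted-repeat copies) and characterization of the four IR-single-copy
    junctions; classification of large-scale IR expansion and contraction;
    gene content, duplication, loss and pseudogenization matrices; signed
    gene-order comparison calling inversions and relocations; SSR, tandem and
    dispersed repeat profiling; syntenic intergenic/intron locus extraction
    with a sequence-variability statistic for marker screening; per-site
    substitution-rate estimation on a fixed ultrametric tree with
    phylogenetic-informativeness profiles; and desk-scale distance/NJ
    phylogenetics with bootstrap support and Robinson-Foulds comparison.
    Includes a seeded simulator of quadripartite plastome evolution
    (junction shifts, gene loss, pseudogenization, inversions, planted
    repeats) with a ground-truth log, so every stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    ape,
    phangorn,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
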