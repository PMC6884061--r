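Package: polycensus
Title: Homoeolog Census, Variant Multiplicity and Synteny Analysis for
    Polyploid Gene Spaces
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing the gene space of highly polyploid genomes
    against a diploid outgroup reference: assignment of polyploid gene copies
    (homologs and homeologs) to single-copy anchor genes with copy-number
    estimation, divergence profiling across coding sequences and upstream
    promoter windows, frameshift versus frame-preserving indel spectra,
    classification of variant sites by allelic multiplicity (mono- to
    tetra-allelic) and predicted large-effect consequence, collinear synteny
    block detection from union-find ortholog groups with a Monte Carlo
    chromosome-fragmentation null model, and per-copy expression tallies.
    A synthetic allopolyploid genome generator with fully recorded ground
    truth drives validation of every stage, so the whole pipeline is testable
    without a multi-gigabase assembly.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    data.table,
    jsonlite,
    yaml,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors,
    withr,
    methods,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse
Config/testthat/edition: 3
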