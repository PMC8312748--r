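Package: probeforge
Title: Design and Optimization of Target-Enrichment Probe Sets in Duplicated Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing custom hybrid-capture bait target sets from
    annotated genomes of lineages with a shared whole-genome duplication, and
    for optimizing universal probe references (Angiosperms353-style) toward a
    focal genome. Implements a BLAST-like exact local-alignment engine, a
    filter cascade that discovers single-copy and once-duplicated loci with
    controlled paralog divergence, exon and intron target extraction with
    greedy collapse, best-representative reference optimization with per-exon
    trimming, locus-recovery statistics on HybPiper-style seq_lengths tables,
    alignment trimming and parsimony-informative-site summaries, and a
    synthetic annotated-genome simulator with machine-readable truth tables
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    methods,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    pheatmap
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
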