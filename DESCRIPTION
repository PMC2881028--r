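Package: srnatile
Title: Discovery of Bacterial Small RNAs from Genome Tiling Arrays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: End-to-end analysis of genome tiling-array experiments for the
    discovery of candidate non-coding RNAs in bacterial intergenic regions.
    Extracts intergenic regions from an annotated (multi-replicon, possibly
    circular) genome, maps literature-predicted ncRNA sequences onto them with
    a seed-and-extend local aligner and Karlin-Altschul E-value statistics,
    normalizes tiling probe intensities against an artificial reference array
    by anchored loess, summarizes probe-level signal per region by Tukey
    median polish, calls expressed and differentially expressed regions with a
    robust inverse-normal noise threshold, and profiles the results by
    hierarchical clustering, genomic density and hotspot scanning, and
    cross-species conservation. A deterministic synthetic-data generator
    emulates the study design (five conditions, 60-mer probes at 13 bp
    spacing) so that every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    methods,
    Rcpp,
    jsonlite,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    ape
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
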