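Package: lg4scape
Title: Long G-Quadruplex Enhancer Discovery and Pore-C Contact Mining
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for discovering long G-quadruplex-rich loci (LG4s) by
    GGG-repeat density scanning, quantifying the G-triplet capacity of gene
    promoters, testing enhancer-annotation overlap enrichment against
    length- and composition-matched control loci, and mining Pore-C
    concatemer reads for single-molecule co-occurrence of an LG4 enhancer
    and its candidate target promoters. Includes a seeded synthetic-data
    generator (genomes with planted LG4 blocks, G-triplet-enriched
    promoters and duplications; DpnII-digested, proximity-ligated
    concatemer reads) so the full pipeline is testable end to end without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    Rcpp,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
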