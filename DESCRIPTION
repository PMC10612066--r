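Package: phagemosaic
Title: Comparative Genomics of Temperate Phage Mosaicism, Retroelement
    Hypermutation, and Prophage Integration
Version: 0.1.0
Authors@R:
    person("Maintainer", "phagemosaic", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for comparative analysis of small temperate phage
    genomes: per-protein percent-identity profiling of a query proteome
    against reference proteomes, median-based summaries of genome modules
    and exact change-point segmentation of module boundaries, two-exemplar
    bipartition of a phage panel into tail lineages,
    diversity-generating-retroelement (DGR) template/variable repeat
    detection with an exact binomial test of adenine-directed
    hypermutation, prophage localisation with attL/attR core-repeat
    discovery and disrupted-gene reconstruction checks, near-identical
    genome differencing with effect classification, read-pileup allele
    fractions, and a sigma-70 consensus promoter scan.  A synthetic-data
    module generates mosaic phage families, DGR cassettes, lysogens and
    mixed-variant pileups so that the whole pipeline runs with no
    external data.
License: MIT
Encoding: UTF-8
Imports:
    BiocGenerics,
    Biostrings,
    methods,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
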