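Package: circRPL
Title: Downstream Analysis of circRNA Back-Splice Junctions in Recurrent Pregnancy Loss Tissue RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Consolidates circRNA back-splice junction (BSJ) calls from two
    detectors (DCC-style and CIRI2-style tables) by exact-coordinate
    intersection, attaches junction-read quantification, flags known versus
    novel circRNAs against a reference catalogue, classifies circRNAs as
    exonic, intronic or intergenic against a gene annotation and assigns
    standardized names, classifies cross-species conservation of back-splice
    sites through interval-map coordinate lifting, performs negative-binomial
    Wald differential expression with library-size offsets and
    Benjamini-Hochberg correction, and runs hypergeometric over-representation
    analysis of host genes. Ships a synthetic-data generator that emulates
    detector outputs and negative-binomial junction counts with planted ground
    truth, so every stage is testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    methods,
    yaml,
    igraph,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
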