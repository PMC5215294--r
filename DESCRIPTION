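Package: epipoise
Title: Epigenomic Poising Analysis of Naive and Memory T Cells from ChIP-Seq Islands
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for asking whether differential gene inducibility between
    naive and memory CD4 T cells is explained by gain or loss of activating
    histone-modification islands. Implements fragment-extended depth-normalized
    ChIP-Seq coverage, average tag-density metaprofiles around transcription
    start sites, FPKM-threshold classification of expressed, silent and
    inducible genes, a Poisson scanning-window island caller, M-A (MAnorm-style)
    normalization with an exact conditional test for differential islands,
    window-based association of differential islands with genes, and a seeded
    synthetic-data generator that plants poised genes and enrichment islands
    with full ground-truth labels so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
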