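Package: panbubble
Title: Colored Superbubble Decomposition, Coordinates and Small-Variant
    Calling for Pangenome de Bruijn Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds a colored de Bruijn graph from a set of highly similar
    haplotype genomes (one sequence per sample), decomposes it into colored
    superbubbles organized as a forest, and derives a tri-tuple coordinate
    system (offset, bubble, color) for bases and a six-tuple system for
    paths. Longest-path offset values computed by a postorder-like traversal
    drive a node-based caller for substitutions and small indels (< 50 bp),
    reported as VCF against a designated reference sample. Cycles caused by
    repeats are detected from early-finishing traversals, located as offset
    intervals, and resolved by scoring cutting regions (R = L/t) and
    splitting the input sequences. Includes a mitogenome-like population
    simulator and location- or type-mapped precision/recall evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    BiocGenerics,
    igraph,
    optparse,
    rtracklayer,
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
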