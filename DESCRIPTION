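Package: plastomarker
Title: Plastome Structure, Diversity and Phylogenetic Marker Survey
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Comparative analysis of annotated chloroplast genomes
    (plastomes) and survey of candidate phylogenetic markers. Determines
    the quadripartite architecture (LSC, SSC, and the two inverted
    repeats) of a circular plastome by exact inverted-repeat detection,
    computes per-region composition tables and screens coding sequences
    for putative pseudogenes. Partitions a whole-plastome multiple
    alignment into coding, non-coding and intergenic-spacer markers,
    computes per-marker diversity statistics (variable sites, parsimony
    informative sites, Kimura two-parameter distances, nucleotide
    diversity with sliding windows), infers neighbor-joining trees with
    nonparametric bootstrap, ranks markers by a weighted mean of relative
    information values, assembles top-k concatenated datasets and picks
    PCR primer pairs for short markers. Includes a sequence simulator
    that evolves plastome-like alignments along a known tree for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
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
    yaml
Suggests:
    optparse,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
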