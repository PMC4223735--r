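Package: mitorearr
Title: Comparative Analysis of Mitochondrial Gene Rearrangements
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative analysis of vertebrate mitochondrial
    genomes centred on gene rearrangement: clover-leaf folding and
    anticodon-based identity assignment of mitochondrial tRNA genes,
    detection of tRNA identity reassignment among paralogs, inference of
    tandem duplication-random loss (TDRL) rearrangement events from
    circular gene orders, pseudogene assessment of duplicated
    protein-coding genes, stem-loop and tandem-repeat annotation of
    noncoding regions, and chi-square tests for codon-usage deviation.
    Includes a fully seeded synthetic mitogenome generator so that every
    analysis stage can be exercised against known ground truth.
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
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    withr
Suggests:
    ape,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
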