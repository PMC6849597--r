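Package: raremag
Title: Targeted Recovery of Rare Genomes from Bulk and Mini-Metagenomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Recovers low-abundance (~1%) bacterial genomes from assembled
    metagenomes by combining tetranucleotide-frequency composition with
    differential coverage across bulk samples, then refining candidate bins
    with coverage-profile compatibility, taxonomic consistency and
    co-occurrence in cell-sorted, MDA-amplified mini-metagenome wells.
    Includes a synthetic-community simulator for end-to-end benchmarking,
    bin quality statistics (N50, single-copy-marker completeness and
    contamination, relative abundance), percentage-of-conserved-proteins
    (POCP) genus delineation, neighbor-joining phylogenetics with
    Jukes-Cantor correction and bootstrap support, and design of
    clade-specific 16S rRNA signature oligonucleotides.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    ape,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
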