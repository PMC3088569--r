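Package: srnapipe
Title: Small RNA-Seq Tag Annotation and Novel miRNA Hairpin Discovery
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A tidyverse-styled pipeline for annotating small RNA
    deep-sequencing libraries of fixed-length reads: collapsing raw reads
    into abundance-ranked unique tags, classifying tags by 5'/3' adaptor
    content, exact dual-end alignment to a genome through a k-mer index,
    hierarchical annotation against repeat/ncRNA/miRNA/RefSeq/EST interval
    tracks, counts-per-million expression summaries with miRNA family
    aggregation, and discovery of novel miRNA precursors by folding
    flanking genomic windows with a nearest-neighbour minimum-free-energy
    model and screening hairpins against explicit structural criteria.
    Includes a synthetic-data generator that plants known and novel miRNAs
    with machine-readable ground truth so every stage is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    tibble,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
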