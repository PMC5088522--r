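Package: phylomark
Title: Gene Age Hallmarks and Coexpression Structure of Tissue Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Dates protein-coding genes by the lowest common ancestor of their
    ortholog groups on a time-calibrated taxonomy lineage, bins gene ages into
    eight evolutionary hallmark stages, classifies house-keeping and
    tissue-enriched genes from multi-tissue RNA-Seq FPKM profiles, and builds a
    resampling-validated Spearman coexpression network whose densely connected
    modules are summarised by gene age composition. Ships a synthetic-data
    generator with planted ground truth (gene classes, gene ages, coexpressed
    modules) so the whole pipeline is testable without external downloads, plus
    hypergeometric term enrichment with Benjamini-Hochberg correction.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    igraph,
    ape,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
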