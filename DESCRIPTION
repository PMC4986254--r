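Package: hkgselect
Title: Identification and Validation of Stable Housekeeping Genes from
    Expression and qPCR Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A screening strategy for housekeeping (reference) genes in
    RNA-seq and qRT-PCR experiments. Normalizes tag-count matrices by coding
    sequence length and sequencing depth, collapses isoform counts, applies
    quantile normalization, ranks genes by expression breadth (proportion of
    samples with zero expression) and coefficient of variation, filters out
    candidates co-regulated with transcription-factor hubs in a
    protein-interaction network, and validates candidate panels with
    comparative threshold-cycle (C_T) stability statistics, leave-one-out
    panel correlations, cross-platform concordance, and cohort-wide
    distribution statistics. Ships a seeded synthetic-data generator with
    planted ground truth for end-to-end evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    limma,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
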