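Package: consistentprot
Title: Consistency-Based Differential Abundance for Paired Knockdown Proteomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for label-free proteomics of paired
    knockdown versus non-targeting-control designs, as used in siRNA
    knockdown studies of skin organoids. Reads MaxQuant proteinGroups-style
    quantitation tables, removes reversed-sequence decoys and contaminants,
    subtracts blank-run keratin background, normalizes to the lowest total
    protein abundance, and classifies proteins as consistently up- or
    down-regulated from per-donor knockdown/control ratios using
    direction-agreement and fold-ratio rules rather than significance
    thresholds. Includes iBAQ computation, technical-replicate Pearson
    correlation QC, volcano statistics from paired t-tests on
    log10-transformed data, hypergeometric over-representation analysis
    against GMT gene sets with Benjamini-Hochberg FDR, delta-delta-Ct qPCR
    fold changes, histology thickness summaries, and a synthetic-data
    generator with known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble
Suggests:
    ggplot2,
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
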