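Package: evmorph
Title: Single-Cell Morphological Bioactivity Profiling of Microglia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: A high-content morphological bioactivity assay for quantifying
    how extracellular-vesicle (EV) treatment shifts cytokine-stimulated
    microglia back toward an unstimulated phenotype, together with companion
    secretome, lipidome and proteome analysis stages. Provides CellProfiler
    style single-cell shape and mitochondrial descriptors with quality-control
    filters, per-well median aggregation, control-anchored min-max
    normalization, PCA composite phenotype scores, Z'-factor assay quality,
    dose-response summaries, Welch-test differential panels, lipid class
    totals, empirical-Bayes moderated differential abundance with a fold
    change rule, a gene set variation analysis (kernel-ECDF rank random walk)
    implementation, and a synthetic-data module that emulates the assay's
    plates, segmented images and omics tables with recorded ground truth.
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
    grDevices,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
Suggests:
    limma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
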