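Package: nichefates
Title: Mapping Metastasizing Tumor-Cell Fates in the Lung Vascular Niche
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable implementation of a computational pipeline for mapping
    the early fates of metastasizing tumor cells in the lung: quality control
    and housekeeping-panel normalization of single-cell count matrices,
    control-binned gene-module scoring, threshold-based endothelial subtype
    classification, cell-cycle scoring with selection of bona fide latent
    tumor cells, pseudobulk differential expression (Wilcoxon rank-sum and a
    simplified negative-binomial Wald engine), all-vs-all marker-panel
    derivation, quasibinomial log-odds deconvolution of aCap/gCap capillary
    composition in bulk samples, a dual-comparison ligand-receptor screen for
    trajectory-defining genes, and region-level bisulfite methylation
    analysis with hypomethylation and sealed-region calls plus
    methylation-array beta/M-values with bead-level testing. A synthetic-data
    generator with attached ground truth emulates the statistical structure
    of each input so the whole pipeline is testable end to end without
    external data.
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
    IRanges,
    limma,
    MASS,
    Matrix,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
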