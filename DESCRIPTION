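Package: survfuse
Title: Multi-Modal Feature Fusion for Breast Cancer Survival Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for multi-modal cancer survival classification at the
    five-year cutoff. Provides a seeded synthetic multi-omics cohort
    generator emulating the modality structure of TCGA-style breast cancer
    data (clinical, copy number, DNA methylation, miRNA, mRNA, and
    whole-slide-image patch embeddings), per-modality preprocessing
    (missingness filtering, weighted k-nearest-neighbour imputation,
    min-max normalisation, expression discretisation, variance-based
    feature selection, patient-id intersection), two engineered feature
    pathways (PCA at a fixed explained-variance target and a variational
    autoencoder with a log-cosh reconstruction loss), whole-slide-image
    patch-bag aggregation, classifier evaluation under stratified
    cross-validation with minority upsampling, and the full
    modality-combination ablation with across-combination stability
    summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
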