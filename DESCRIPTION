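Package: cflmd
Title: Cell-Free DNA Methylation Analysis and Diagnostic Modelling for Lupus
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for building cell-free DNA methylation
    diagnostic models of systemic lupus erythematosus and lupus nephritis.
    Covers consensus differential screening across multiple HM450 array and
    expression cohorts, whole-genome bisulfite sequencing (WGBS)
    differentially methylated position and region calling with dispersion
    shrinkage, binomial subsample augmentation, cross-platform feature
    integration, a three-hidden-layer neural-network diagnostic score with
    ROC/AUC evaluation and disease-activity correlation, and
    immune-microenvironment annotation (reference-based methylation
    deconvolution, single-sample gene-set enrichment, over-representation
    and pre-ranked enrichment analysis). Ships a synthetic-data generator
    with known ground truth so the whole pipeline is testable without
    external downloads.
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
    pracma,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    fgsea,
    jsonlite,
    limma,
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
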