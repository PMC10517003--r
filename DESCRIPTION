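Package: gliotex
Title: Texture-Feature Analysis of Diffusion MRI for Glioma Grading
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for grading gliomas from apparent
    diffusion coefficient (ADC) maps of diffusion-weighted MRI. Computes ADC
    parametric maps from multi-b-value image pairs, extracts higher-order
    moment and grey-level co-occurrence matrix (GLCM) texture features from
    tumor regions of interest, balances classes with SMOTE, selects features
    by the one-way ANOVA F statistic, and trains and evaluates multiclass
    classifiers (cross-validated algorithm comparison, tuned random forest,
    per-class precision/recall/F1 and one-vs-rest ROC AUC). Includes a
    synthetic phantom-cohort generator with class-dependent diffusivity and
    texture heterogeneity so the whole pipeline is testable without patient
    data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    class,
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    nnet,
    pROC,
    png,
    purrr,
    ranger,
    readr,
    rlang,
    RNifti,
    rpart,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
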