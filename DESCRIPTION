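Package: sextme
Title: Sex Differences in the Tumor Microenvironment from Bulk Genomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for quantifying sex differences in the
    tumor immune microenvironment from bulk expression and somatic mutation
    data. Computes per-sample tumor mutational burden (TMB), single-sample
    GSEA immune-cell enrichment scores, ESTIMATE-style immune/stromal scores
    and tumor purity; tests male-versus-female differences in these features
    with rank-sum and t tests under Benjamini-Hochberg control; compares the
    TMB-microenvironment correlation structure between sexes via the Fisher
    z-transformation; runs phenotype-permutation GSEA on immune pathways;
    detects sex-biased mutated genes and their immune-cell associations;
    builds sex-specific immune-cell prognostic risk scores with Cox models
    and Kaplan-Meier stratification; and evaluates TMB as a predictor of
    immune-checkpoint-blockade response. A synthetic-cohort generator with
    planted sex effects provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    survival,
    withr,
    stats,
    utils,
    generics
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
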