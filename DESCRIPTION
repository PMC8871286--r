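Package: dixonvol
Title: Whole-Liver Dixon MRI Volumetrics for Hepatic Steatosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for quantifying liver fat from two-point Dixon MRI and
    single-voxel MR spectroscopy (MRS). Computes voxel-wise signal
    fat-fraction (PDFF) maps from water/fat or in-phase/opposed-phase
    images, relaxation-corrected MRS PDFF, the volumetric steatosis
    statistic LV% (percentage of liver volume with PDFF above a
    threshold), ROC/Youden derivation of steatosis cutoffs against MRS
    labels, and the paired two-arm comparison statistics used in dietary
    intervention studies (Bland-Altman agreement, Spearman correlation,
    Wilcoxon tests, two-way repeated-measures ANOVA). Includes a seeded
    synthetic cohort generator producing 3D liver phantoms with known
    ground truth, so the whole pipeline is testable end to end without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
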