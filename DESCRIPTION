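Package: ivimpref
Title: IVIM and ADC Model Fitting, Voxel-Wise Model Preference and
    Repeatability Statistics for Diffusion-Weighted MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Voxel-wise fitting of mono-exponential (apparent diffusion
    coefficient, ADC) and bi-exponential (intra-voxel incoherent motion,
    IVIM) signal models to multi-b-value diffusion-weighted MR volumes,
    with corrected Akaike information criterion (AICc) model comparison,
    model preference maps and the p_IVIM biomarker (the fraction of
    region-of-interest voxels better described by the IVIM model).
    Includes the segmented IVIM fit with b-value cut-off sweep, ADC fits
    on configurable b-value subsets (ADC_b0, ADC_b150) and the
    perfusion-bias statistic deltaADC, ROI-level biomarker summaries,
    test-retest repeatability (within-subject coefficient of variation),
    repeated-measures ANOVA with Bonferroni-corrected post-hoc contrasts
    and repeated-measures correlation, plus deterministic multi-tissue
    digital phantoms with Gaussian or Rician noise for end-to-end
    validation without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    minpack.lm,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
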