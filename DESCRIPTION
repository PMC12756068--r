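Package: frocdwi
Title: Fractional-Order-Calculus Diffusion MRI Analysis of Breast Lesions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Voxel-wise fitting of the fractional-order-calculus (FROC)
    diffusion signal model and the mono-exponential ADC model to multi-b
    diffusion-weighted MRI, fuzzy C-means whole-lesion segmentation grown
    from a 2D seed ROI, whole-lesion first-order histogram features
    (percentiles, mean, median, entropy, kurtosis, skewness), and the
    cohort-level statistical battery used for diffusion biomarkers
    (Mann-Whitney, Kruskal-Wallis with Bonferroni pairwise correction,
    Spearman correlation, two-way random-effects ICC, ROC/Youden analysis
    and the DeLong test). Includes synthetic multi-b phantoms with Rician
    noise and synthetic lesion cohorts so the full pipeline runs without
    any image download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    MASS,
    RNifti,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    e1071,
    pROC,
    jsonlite,
    withr
Config/testthat/edition: 3
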