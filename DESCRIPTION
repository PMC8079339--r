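Package: iplconcord
Title: Validating Intraprostatic Lesion Contours Against Biopsy Sector Landmarks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, fully synthetic testbed for validating intraprostatic
    lesion (IPL) delineation from PSMA-PET and multiparametric MRI against
    biopsy-derived sector landmarks. Provides a digital prostate phantom with
    known ground-truth lesions (partial-volume blurring, noise, observer
    variability), a 36-sector schematic of the gland with simulated systematic and
    targeted biopsy sampling, landmark-based rigid plus thin-plate-spline
    registration of the sector schematic onto axial slices, fractional-SUVmax
    automatic contouring with dominant-lesion selection and physical margin
    expansion, sector-level overlap scoring (Dice similarity coefficient, Youden
    index, sensitivity, specificity) with best-threshold selection, and the
    statistical layer (Kolmogorov-Smirnov screening, Kruskal-Wallis comparisons,
    point-biserial predictive-factor correlations).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    dplyr,
    tidyr,
    tibble,
    purrr,
    readr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    withr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
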