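Package: cesmr
Title: Quantitative Enhancement Analysis for Contrast-Enhanced Spectral
    Mammography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for quantitative analysis of breast-lesion enhancement on
    contrast-enhanced spectral mammography (CESM) subtraction images:
    contrast-to-noise ratio (CNR) measurement from lesion and background
    regions of interest, relative signal difference (RSD) and four-way
    kinetic enhancement-pattern classification from the two sequential
    projections, and the diagnostic-performance statistics used to compare
    benign and malignant lesions (nonparametric group tests with Bonferroni
    correction, empirical ROC curves with Youden cut-offs, DeLong paired AUC
    comparison, and Cohen's kappa agreement against DCE-MRI time-intensity
    curve categories). Includes a calibrated synthetic cohort and phantom
    image generator so the full pipeline can be exercised and validated
    without clinical data.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr
Suggests:
    e1071,
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
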