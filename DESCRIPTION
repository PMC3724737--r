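Package: marginsense
Title: Quantitative Spectral-Imaging Analysis of Breast Tumor Margins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for intra-operative breast tumor margin assessment
    from quantitative optical parameter maps (beta-carotene concentration, total
    hemoglobin, and wavelength-averaged reduced scattering). Reduces per-margin
    maps to distributional image-descriptive variables (median, quantile-threshold
    pixel fractions, Kolmogorov-Smirnov statistics against a positive-margin
    reference pool), tests distribution shifts with blocked-permutation
    Kolmogorov-Smirnov statistics, classifies margins with a breast-density
    stratified conditional inference tree whose significance is assessed by label
    permutation, and quantifies adipocyte morphometry (cell count, density, area)
    from histology images via bilateral filtering and Canny edge detection. A
    synthetic-cohort module generates margin images and packed-adipocyte histology
    fixtures with recorded ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tools,
    stats,
    utils,
    jsonlite,
    EBImage,
    png
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
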