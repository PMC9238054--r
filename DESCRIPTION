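Package: lsfgflow
Title: Superpixel and Peripapillary Blood-Flow Analysis for Laser
    Speckle Flowgraphy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies retinal and choroidal blood flow from laser speckle
    flowgraphy (LSFG) mean-blur-rate (MBR) composite maps. Implements the
    standard peripapillary analysis (concentric annuli around the optic
    nerve head with histogram thresholding into superficial retinal vessel
    flow, MV, and choroidal tissue flow, MT) and a whole-scan superpixel
    analysis (SLIC segmentation, per-superpixel mean MBR, five categorical
    flow ranges and percent-area histograms), together with ocular
    perfusion pressure computation and paired-eye cohort statistics
    (paired t-tests, flow-versus-time regressions, Spearman correlation
    matrix). Includes a seeded synthetic paired-eye cohort generator with a
    programmable irradiation effect so the full pipeline is testable
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    tiff,
    readr,
    withr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
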