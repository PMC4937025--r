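Package: fmrihub
Title: Whole-Brain Degree Centrality and Directed Connectivity Mapping for Resting-State fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Voxel-wise functional network-architecture analysis of resting-state
    BOLD fMRI: temporal/spatial preprocessing (volume discard, Gaussian smoothing,
    linear detrending, ideal band-pass filtering), gray-matter-masked voxel-wise
    degree centrality with correlation thresholding and z-standardisation,
    Monte-Carlo cluster-extent correction of statistic maps, seed-based bivariate
    Granger causality mapping, covariate-adjusted group inference and clinical
    correlation reports, plus a synthetic two-group BOLD cohort generator with
    injected hub and directed-coupling effects for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
LinkingTo:
    Rcpp,
    RcppArmadillo
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    igraph,
    MASS,
    optparse,
    withr
Config/testthat/edition: 3
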