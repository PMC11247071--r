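Package: spectpareto
Title: Pareto Optimization of Quantitative Lu-177 SPECT Acquisition and
    Reconstruction Settings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates quantitative Lu-177 SPECT of sphere and
    anthropomorphic phantoms, resamples time-binned projection data to
    emulate reduced-time and reduced-angle acquisitions, reconstructs
    images with OS-EM under a constrained subset/iteration scheme with
    attenuation, distance-dependent resolution and additive scatter
    compensation, quantifies volume-of-interest activity concentrations
    against calibration phantoms, and identifies Pareto fronts of bias
    (absolute mean relative error) versus precision (coefficient of
    variation over noise realizations).
License: MIT
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
    readr,
    jsonlite,
    yaml,
    generics,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
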