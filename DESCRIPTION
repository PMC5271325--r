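Package: comreach
Title: Bayesian Observer Models of Error Correction in Center-of-Mass Reaching
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates and fits a Bayesian observer model of a center-of-mass
    reaching task in which covert visual perturbations of the cursor reveal
    uncertainty-dependent partial error correction. The observer combines a
    trimodal Gaussian-mixture prior over disk log-radius-ratios with noisy
    measurements, maps beliefs to center-of-mass space, and selects endpoints
    by minimizing an inverted-Gaussian error loss plus a weighted adjustment
    (effort) cost. Includes a synthetic session generator emulating the task's
    stimulus and perturbation statistics, maximum-likelihood parameter fitting
    with a parameter-recovery harness, the residual-error/slope/score analysis
    pipeline, alternative observer variants (quadratic error loss, power-law
    adjustment loss, miscalibrated cursor), and ggplot2 figures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    lhs,
    pracma,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
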