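Package: ricecable
Title: Level-Crossing Firing Rates for Spatially Extended Neuron Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analytical and simulation tools for the low-rate firing regime of
    passive neuron models with spatial structure (dendrites, axon and soma)
    driven by distributed, temporally filtered stochastic synaptic input.
    Computes the mean, standard deviation and rate-of-change standard
    deviation of the subthreshold voltage at a spike-trigger point -- in
    closed form for single and paired semi-infinite dendrites, and by
    frequency-domain quadrature of the voltage power spectrum for composite
    morphologies -- and converts them into firing-rate estimates with Rice's
    level-crossing formula. A stochastic cable-equation simulator
    (Euler-Maruyama, compiled stepping kernel) with an integrate-and-fire
    threshold-reset mechanism provides ground truth for every analytic
    result. Includes parameter calibration, morphology sweeps, and tidy
    tabular outputs throughout.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
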