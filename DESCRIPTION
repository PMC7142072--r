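Package: jellysmc
Title: Jellyfish Carbon-Budget Modelling and Statistical Model Checking
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
                  role = c("aut", "cre"))
Description: A zero-dimensional ecophysiological carbon-budget model of the
    scyphozoan jellyfish Pelagia noctiluca (predation, ingestion,
    assimilation, respiration, excretion, reproduction, egestion) driven by
    temperature and prey concentration, together with a statistical model
    checking engine that calibrates the unknown parameters: candidate
    parameter vectors are enumerated on a grid, wrapped in uniform
    uncertainty intervals, scored by Monte Carlo estimation of the
    probability that random simulations stay inside observation tunnels, and
    pruned early with Wald's sequential probability ratio test. Includes
    laboratory and in-situ calibration scenarios, a synthetic-data generator
    for end-to-end parameter-recovery experiments, and conversion of modelled
    egestion into particulate organic carbon export at depth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
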