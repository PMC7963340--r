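Package: srincidence
Title: Senescent-Cell Threshold Models of Age-Related Disease Incidence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Stochastic saturated-removal (SR) modelling of senescent-cell
    accumulation and the incidence of age-related diseases. Implements the
    SR stochastic differential equation with first-passage disease onset,
    closed-form two-parameter (threshold, susceptible fraction) and
    three-parameter (threshold distribution) incidence curves, weighted
    least-squares fitting of observed incidence-versus-age tables,
    individual-level synthetic cohort generation, simulation of intermittent
    senolytic treatment schedules, and progenitor/differentiated-cell tissue
    homeostasis circuits whose collapse under senescent-cell load yields
    threshold-type incidence. A command-line interface exposes the main
    computations for shell pipelines.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    deSolve,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
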