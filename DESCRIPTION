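Package: portersim
Title: Kinetic and Thermodynamic Simulation of Membrane Sugar Transporter Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Steady-state and time-course simulation of mass-action transport
    networks for facilitated sugar transport: alternating-access (mobile
    carrier) models and fixed-site staged-diffusion models, with the standard
    transport protocols (zero-trans net flux, equilibrium isotope exchange,
    counterflow), Michaelis-Menten saturation fitting, inverse calibration of
    carrier rate constants to kinetic observables, and thermodynamic
    consistency audits (detailed-balance cycle products, Gibbs free-energy
    relations for asymmetric rates and affinities, activity-coefficient
    reciprocity, Haldane ratios).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    lhs,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
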