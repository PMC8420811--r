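Package: ttcgs
Title: Time-to-Contact Estimation for Parabolic Trajectories from
    Monocular Optics with Gravity and Size Priors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation toolkit for interceptive timing in the outfielder
    problem. Generates ball trajectories under gravity and aerodynamic drag,
    projects them into the egocentric optical variables available to a
    stationary or moving observer (retinal size, its rate of expansion, the
    elevation angle and its rate of change), and evaluates the GS
    (gravity-size) time-to-contact estimator that calibrates those optics
    with internalized priors for gravitational acceleration and physical
    ball size. Includes Weber-fraction noise propagation by Monte Carlo,
    maximum-likelihood cue combination with Tau, a Bayesian
    population-coding encode/decode experiment with Gaussian tuning curves
    and Poisson spiking, canonical study scenarios, and a configuration
    driven runner with tidy CSV/JSON output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
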