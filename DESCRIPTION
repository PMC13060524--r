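Package: ffpcsim
Title: Simulation and Analysis of Burst-Firing Fiber Fabry-Perot Microcavity Sensors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for modelling label-free single-molecule detection with a
    Pound-Drever-Hall locked fiber Fabry-Perot microcavity (FFPC) driven into a
    photothermal burst-firing regime. Provides closed-form cavity optics
    (finesse, Q, Gaussian mode geometry, transmission and error-signal
    lineshapes), Brownian single-molecule transit simulation with
    Stokes-Einstein diffusion and perturbative resonance shifts, a stochastic
    integrator for the coupled optical-thermal-servo lock dynamics, event
    detection with baseline-dwell burst clustering, pulse-response calibration
    with sigmoidal sensitivity fits and piezo frequency conversion, and
    two-species event-rate differentiation with exact permutation tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
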