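Package: adaptisi
Title: Stochastic Adaptation Currents and Interspike-Interval Statistics
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulators and closed-form theory for perfect integrate-and-fire
    neurons with spike-frequency adaptation carried by a finite population of
    two-state ion channels. Implements the exact Gillespie channel model, its
    diffusion (Langevin) approximation, the white-noise/deterministic-adaptation
    and colored-noise limit cases, and a conductance-based Traub-Miles variant
    with an M-type adaptation current; plus estimators for interspike-interval
    cumulants, rescaled skewness/kurtosis, serial correlation coefficients and
    peristimulus time histograms, and the matching weak-noise analytics
    (inverse-Gaussian and colored-noise ISI densities, weak-noise cumulants,
    limit-cycle serial-correlation theory).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    graphics,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    Matrix,
    optparse
Config/testthat/edition: 3
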