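Package: tetherscope
Title: Extracting Chromatin Tethering Interactions from Single-Locus Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to infer external tethering forces acting on a polymer
    (e.g. the chromatin fiber) from the recorded trajectory of a single
    tagged monomer such as a fluorescently labelled chromosomal locus.
    Provides overdamped Langevin (Euler-Maruyama) Brownian simulation of
    Rouse and beta-polymer bead-spring chains with external harmonic wells,
    closed-form inversion formulas relating the observed monomer's
    conditional drift and stationary variance to the strength and chain
    position of a harmonic tether, and trajectory-side estimators of the
    effective spring constant, diffusion coefficient, conditional drift
    field, mean-square displacement exponent, and position autocorrelation
    with double-exponential fitting.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    minpack.lm,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
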