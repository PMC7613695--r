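Package: surfhop
Title: Trajectory Surface Hopping Photodynamics on Analytic Coupled
    Potential Energy Surfaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale nonadiabatic photodynamics toolkit: harmonic Wigner
    sampling of initial conditions, nuclear-ensemble absorption spectra,
    Tully fewest-switches surface hopping across singlet and triplet
    manifolds with spin-orbit coupling and energy-based decoherence,
    linear-interpolation reaction paths in mass-weighted internal
    coordinates, relaxed scans and penalty-function optimization of
    minimum-energy crossing points. Dynamics run on analytic coupled
    diabatic surface models, including a calibrated reduced-dimensional
    surrogate of the 2-thiooxazole excited-state landscape with a bright
    pi-pi* state, a dark n-pi* state and repulsive pi-sigma* states along
    the C(2)-O and N-H stretches.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    deSolve,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
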