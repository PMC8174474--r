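Package: vastra
Title: Active-Learning Physics-Informed Surrogates for Parametric Tube Flow
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trains a physics-informed neural network surrogate for steady
    incompressible Navier-Stokes pressure and velocity fields over a
    two-dimensional design space (tube shape, inflow rate), using
    residual-based active learning. An integrated parametric mesh generator
    and Taylor-Hood finite-element solver act as the oracle that produces
    nodal training data on demand. The surrogate predicts a stream function
    and pressure, so its velocity field is divergence-free by construction;
    all spatial derivatives entering the momentum-residual loss are exact
    analytic derivatives of the network. Includes the random and uniform
    sampling baselines, L2 field-error and boundary-error diagnostics, and
    an inverse-design pressure sweep over tube geometries.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
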