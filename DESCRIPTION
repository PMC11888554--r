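Package: clds
Title: Conditionally Linear Dynamical Systems for Neural Population Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits latent linear-Gaussian state-space models whose parameters
    (dynamics, bias, emission, and initial-state functions) vary nonlinearly
    with observed experimental covariates such as head direction or reach
    angle. Approximate Gaussian-process priors over the parameter functions
    are realized with truncated Fourier feature bases, so that conditioned on
    the covariate sequence the model is an exact time-varying linear dynamical
    system. Provides Kalman filtering and smoothing, closed-form
    expectation-maximization with Sylvester-equation regression updates,
    a synthetic head-direction ring-attractor generator, and evaluation and
    interpretation tools (co-smoothing, composite dynamics fields, analytic
    fixed points, dynamics spectra, and model tuning curves).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
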