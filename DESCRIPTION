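Package: vibspec
Title: Time-Averaged Vibrational Power Spectra from Molecular Dynamics
    Trajectories
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes positive-definite, time-averaged vibrational power
    spectra from classical molecular dynamics trajectories via the Fourier
    transform of velocity (or normal-mode momentum) autocorrelation
    functions.  Builds an orthogonal normal-mode basis from a mass-weighted
    Hessian so that Cartesian trajectories can be projected onto individual
    vibrational modes and spectral peaks assigned mode by mode.  Includes
    parsers for block-format Cartesian trajectories, normal-mode momentum
    trajectories and Tinker velocity dumps, an optional Eckart-frame
    alignment, synthetic harmonic and Morse trajectory generators with known
    analytic spectral content, and a command-line driver.
License: MIT
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    stats,
    graphics,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
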