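Package: tumorcal
Title: Sequential Bayesian Calibration of Avascular Tumor Growth Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calibrates a hierarchy of avascular tumor growth models against
    in vitro viability time courses and time-resolved spatial cell
    distributions. Provides reduced ordinary-differential-equation models of
    apoptosis, logistic proliferation and nutrient-gated necrosis, a 2D
    Cahn-Hilliard phase-field model with degraded mobility solved by an
    energy-stable convex-splitting scheme, Gaussian and Pearson-correlation
    likelihoods, adaptive Metropolis sampling with posterior-to-prior
    propagation across calibration stages, posterior-predictive bands, an
    L1 distance between cumulative distribution functions as the calibration
    error, leave-one-replicate-out cross-validation, and a synthetic study
    generator with known ground truth for end-to-end parameter-recovery
    experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    tiff,
    yaml
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite,
    withr
Config/testthat/edition: 3
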