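Package: latentgeom
Title: Geometry of Multitask Readout from Neural Population Codes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analyzing how the geometry of a neural population code
    determines the generalization error of supervised Hebbian readouts averaged
    over many binary classification tasks. Implements four geometric statistics
    of a Gaussian code (neural-latent correlation, participation-ratio
    dimension, signal-signal factorization and signal-noise factorization), a
    closed-form task-averaged generalization error, construction and numerical
    optimization of error-minimizing codes under the positive-semidefinite
    constraint, synthetic ensembles (power-law Gaussian latents, linear and
    whitened codes, random and trained multitask multilayer perceptrons),
    covariance estimation from finite samples, and estimation of the
    task-relevant subspace dimension from spike counts via Poisson generalized
    linear models with Gaussian basis functions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    glmnet
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
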