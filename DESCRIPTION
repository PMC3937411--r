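Package: noisecorr
Title: Noise Correlations and the Fidelity of Neural Population Codes
Version: 0.1.0
Authors@R:
    person("Analysis", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying how pairwise noise correlations shape the
    accuracy of a neural population code when tuning curves and single-neuron
    variances are held fixed.  Implements three information measures (linear
    Fisher information, optimal-linear-estimator information, and Gaussian
    mutual information), their gradients with respect to noise correlations,
    the sign rule relating signal and noise correlations, the spectrahedron
    geometry of admissible correlation matrices, constrained maximization of
    information over correlations, a constructive noise-cancellation algorithm
    with feasibility tests and solution-set dimension, condition-number
    sensitivity bounds, and synthetic heterogeneous von Mises populations with
    Poisson variability.  A command-line interface exposes the main
    computations on delimited-text matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    Matrix,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
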