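Package: jmblock
Title: Blockwise Bayesian Inference for Joint Longitudinal and Multistate Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Bayesian joint models linking a Gaussian longitudinal biomarker to a
    unidirectional multistate event process through shared random effects and
    trajectory-based association structures. Provides three posterior inference
    strategies: the full joint model (JM-MSM), a blockwise decomposition into
    competing-risk blocks (JM-CR), and a blockwise decomposition into single
    transitions (JM-ST), together with concurrent or historical assignment of
    longitudinal data to blocks. Includes cause-specific hazard likelihoods with
    Gauss-Legendre quadrature, Weibull and log B-spline baseline intensities on
    clock-forward or clock-reset timescales, an adaptive Metropolis-within-Gibbs
    sampling backend, Pareto-smoothed importance-sampling leave-one-out
    cross-validation for blockwise model comparison, and a joint-process
    simulator based on inversion of cumulative transition intensities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    splines,
    pracma,
    MASS,
    yaml,
    jsonlite,
    parallel
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
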