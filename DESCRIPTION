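Package: kmrmix
Title: Bayesian Kernel Machine Regression for Exposure Mixtures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits Bayesian kernel machine regression (BKMR) models for
    estimating the joint health effects of multiple concurrent exposures.
    The multivariable exposure-response surface is modelled through a
    component-weighted Gaussian kernel with spike-and-slab variable
    selection (component-wise or hierarchical over groups of correlated
    exposures), continuous or binary (probit) outcomes, random intercepts
    for clustered data, and an optional Gaussian-predictive-process
    low-rank approximation for large samples. Post-processing tools
    provide posterior inclusion probabilities, cross-sections of the
    fitted surface, and overall, single-exposure, and interactive effect
    summaries with credible intervals, along with convergence diagnostics
    and synthetic-data generators with known truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
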