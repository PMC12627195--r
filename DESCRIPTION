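Package: serialdog
Title: Serial Dependence Analysis with Hierarchical Bayesian
    Derivative-of-Gaussian Models and Mouse Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying serial dependence in continuous-report
    psychophysics. Response errors (and mouse-trajectory deviation
    statistics) are binned by the relative feature value of the previous
    trial and modelled with a first-derivative-of-Gaussian (DoG) bias
    curve, fitted either by deterministic least squares or by a
    hierarchical Bayesian model (participants as random effects, report
    types as fixed effects) sampled with MCMC via JAGS. Includes circular
    statistics utilities, a synthetic experiment generator for
    continuous color-report tasks with mouse tracking, trajectory
    preprocessing (movement-onset detection, time normalization,
    rotation to the target axis, area-under-curve statistics with and
    without endpoint bias), time-resolved bias estimation, convergence
    diagnostics, and an end-to-end pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    rjags,
    coda,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr
Config/testthat/edition: 3
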