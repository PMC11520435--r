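Package: bqrbmi
Title: Bayesian Quantile Regression for Under-Five Child BMI
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Bayesian quantile regression with an asymmetric Laplace
    working likelihood, fitted by a Gibbs sampler that exploits the
    exponential-normal scale mixture representation of the asymmetric
    Laplace distribution (latent mixing variables have generalized
    inverse Gaussian full conditionals at order one half).  Includes
    multi-quantile fitting with equal-tailed credible intervals and
    significance flags, MCMC diagnostics (trace, density,
    autocorrelation), a descriptive anthropometry layer (BMI,
    frequency and percentile tables, within-sample weight-status
    classification), and a synthetic generator for child-level survey
    tables mimicking the 2019 Ethiopia Mini DHS covariate structure.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
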