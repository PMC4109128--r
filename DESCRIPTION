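Package: hsgm
Title: Hierarchical Screened Gaussian Models for Normal Means with
    Uncertain Interval Constraints
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Bayesian inference for a normal mean under an uncertain
    interval constraint via a two-stage (hierarchical screened Gaussian)
    prior. Provides the weighted (interval-screened) normal distribution
    that arises as the marginal prior -- density, sampler, moments and a
    rejection-sampling oracle -- together with the three maximum-entropy
    priors it interpolates (unconstrained normal, doubly truncated
    normal, weighted normal), their differential entropies (closed form
    and Monte Carlo), an objective measure of the degree of uncertainty
    about the interval constraint based on a bivariate-normal rectangle
    probability, conjugate posterior updates, a Gibbs sampler for the
    mean and noise variance, the constraining-effect decomposition of
    the posterior moments, and seeded synthetic-data and calibration
    utilities with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    coda,
    jsonlite,
    mvtnorm,
    stats,
    truncnorm,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
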