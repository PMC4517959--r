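Package: odbinom
Title: Simulation and Estimation for Overdispersed Binomial Mixed Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for studying overdispersion in Binomial mixed models of
    proportion data. Simulates clutch-style proportion datasets under two
    overdispersion mechanisms (a Beta-Binomial mixture, and logit-normal
    noise added to the linear predictor), fits Binomial, Binomial with
    observation-level random effect (OLRE), and Beta-Binomial generalized
    linear mixed models by exact marginal maximum likelihood via
    Gauss-Hermite quadrature, computes the Pearson-residual dispersion
    statistic with a parametric-bootstrap confidence interval, provides an
    adaptive Metropolis-within-Gibbs sampler for the Bayesian Beta-Binomial
    hierarchical model with the Gelman-Rubin diagnostic, and runs replicated
    parameter-recovery simulation studies over configurable scenario grids.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    pracma,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    lme4,
    glmmTMB,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
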