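Package: pestdemog
Title: Deterministic and Stochastic Demography of Stored-Product Insect Cohorts
Version: 0.1.0
Authors@R: person("Demography", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for combined deterministic and stochastic demographic
    analysis of insect cohorts reared at constant temperatures, motivated by
    stored-product pests such as the khapra beetle. Computes cohort life
    tables and the classical demographic parameters (net reproductive rate,
    intrinsic and finite rates of increase, generation and doubling times,
    reproductive value, life expectancy) with bootstrap percentile confidence
    intervals; fits the Briere thermal-performance model to intrinsic-rate
    data; performs Kaplan-Meier and parametric accelerated-failure-time
    survival analysis of time to death and right-censored time to first egg
    with AIC model selection; and fits a Bayesian zero-inflated Poisson model
    of daily fecundity by a purpose-built Gibbs/Metropolis sampler. A seeded
    synthetic cohort generator reproduces the statistical structure of
    stage-structured life-history experiments so the full pipeline is
    testable without external data.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    survival,
    jsonlite
Suggests:
    withr,
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
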