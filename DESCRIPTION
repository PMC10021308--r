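Package: setprior
Title: Spatial Targeting of House-Based Malaria Interventions by
    Beta-Binomial Geostatistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies surveyed households as suitable for Screening + Eave
    Tubes (SET) house modification from wall and roof materials, fits a
    Bayesian beta-binomial logistic geostatistical model with a Matern
    Gaussian process to cluster-level suitability counts, maps posterior
    mean suitability and the exceedance probability of an 80 percent
    suitability threshold on a regular grid, applies transmission- and
    access-based exclusion rules to delineate priority areas, estimates
    covered population and implementation cost, and ranks administrative
    units by a signed z-score sum. Includes a synthetic-data generator that
    reproduces the statistical structure of displaced household-survey
    clusters so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
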