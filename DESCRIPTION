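Package: demopriors
Title: Monte Carlo Demographic Priors for Population Growth Rate and
    Stock-Recruitment Steepness
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Propagates uncertainty in fish life-history traits into
    probability distributions of the intrinsic population growth rate (r)
    and the Beverton-Holt stock-recruitment steepness (h), for use as
    Bayesian priors in stock assessment.  Young-of-the-year mortality is
    built from a stochastic daily growth trajectory combined with the
    McGurk allometric mortality-dry weight regression; r is the log
    dominant eigenvalue of a stochastic Leslie matrix; h is derived from
    recruits-per-spawning-biomass and spawning-biomass-per-recruit
    computed on simulated age-structured populations.  Ships the Atlantic
    bluefin tuna (Thunnus thynnus) parameterization as the default
    configuration, together with scenario presets, correlated (copula)
    sampling, and an acceptance-rejection correction producing priors
    restricted to r >= 0 and h >= 0.2.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
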