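Package: snowcross
Title: Multi-Scale Analysis of Wildlife Road-Crossing Preferences from Snow-Track Surveys
Version: 0.1.0
Authors@R:
    person("Road Ecology", "Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying highway barrier effects on mammal
    communities from winter snow-track surveys and for locating preferred
    crossing sites from multi-scale landscape predictors. Implements
    effort-standardized crossing rates and highway permeability, track
    accumulation curves, maximum-likelihood fitting of Poisson, negative
    binomial, zero-inflated Poisson and zero-inflated negative binomial
    count models, likelihood-ratio and Vuong tests for distribution choice,
    a branching AICc beam search over candidate predictor pools with
    post-hoc significance filtering and Akaike-weight model averaging, and
    composition of per-group abundance predictions into community
    crossing-site preference maps on a 30 m grid. A synthetic-landscape
    generator with known ground truth makes the whole pipeline testable
    without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    optparse,
    withr
Config/testthat/edition: 3
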