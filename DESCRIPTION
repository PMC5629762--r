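Package: imcost
Title: Cost Determinants of Routine Infant Immunization Services
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for multi-country facility-level costing
    studies of routine infant immunization. Provides a synthetic-data
    generator emulating a six-country cluster-sampled facility survey,
    survey-weighted average-cost estimators with multi-stage bootstrap
    confidence intervals, Bayesian hierarchical regressions of log site
    costs with country and province random effects and country-specific
    volume slopes (fitted with JAGS), WAIC model comparison, and
    post-estimation economics: first differences, output elasticities,
    Duan-smearing retransformed cost curves, and volume-quintile
    contrasts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    rjags,
    coda,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
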