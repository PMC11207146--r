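Package: remiforest
Title: Remittance-Mediated Forest Recovery Under Payments for Ecosystem
    Services
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing how migrant remittances mediate the
    socioeconomic and ecological outcomes of payments-for-ecosystem-services
    (PES) reforestation programs, modelled on China's Conversion of Cropland
    to Forest Program. Provides a synthetic two-site household-survey and
    raster generator with planted effects; survey-weighted random-intercept
    logistic and linear models of remittance with marginal effects and
    weighted-bootstrap margin distributions; circular-buffer and ring-buffer
    forest-cover and EVI change metrics with exact fractional cell-overlap
    weighting; propensity-score matching with balance diagnostics and caliper
    sensitivity; pairwise-bootstrap average treatment effects with
    occurrence-of-significance consistency; forest-dependence mechanism
    tests; additionality estimators with uncertainty propagation and
    program-level scaling; and migration/remittance flow tables with
    distance-bin ANOVA.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    lme4,
    purrr,
    rlang,
    stats,
    statmod,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
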