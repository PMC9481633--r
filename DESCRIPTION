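Package: beeload
Title: Pesticide Application Rates, Bee Toxic Load and Landscape
    Pesticide Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Synthesizes state-level pesticide use surveys, census and
    survey crop acreage, and honey bee acute toxicity endpoints into
    compound-level application rates (kg/ha) and an aggregate insecticide
    'bee toxic load' (honey bee lethal doses per hectare, on contact and
    oral toxicity bases) for state by crop-group by year combinations.
    Resolves heterogeneous LD50 endpoints (point estimates, censored
    bounds, regulatory and non-regulatory sources) into consensus values
    with mode-of-action median imputation, harmonizes five-yearly census
    with annual survey acreage via temporal interpolation, builds
    land-cover reclassification tables (including additive double-crop
    accounting and unsurveyed/noncrop flags), reclassifies categorical
    land-cover grids into predicted pesticide loading maps, and provides
    the cross-validation statistics (relative percent difference,
    signed-rank tests, rank and linear correlations) used to check the
    synthesized estimates against an independent survey. A synthetic-data
    generator produces complete fixture bundles with known ground truth so
    the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
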