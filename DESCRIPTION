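Package: herdmass
Title: Cattle Biomass and Stock Value Estimation from Registration and Movement Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Estimates animal-, herd- and national-level cattle biomass (kg)
    and stock value (EUR) from animal registration and movement event data.
    Sex-specific segmented (piecewise) regressions of liveweight and value on
    age, with breed-category, month and year covariates, are trained on
    slaughter-valuation records and applied to monthly first-of-month
    population snapshots reconstructed from the movement log. Herds are
    classified by a configurable decision tree into functional types and
    subtypes, predictions are aggregated by herd, type and sector, and values
    are deflated to real prices with a consumer price index. A synthetic-data
    module generates movement, slaughter, market and CPI datasets with known
    ground truth so that the whole chain is testable without access to
    national databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
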