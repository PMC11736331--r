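Package: vetamc
Title: Quantification of Veterinary Antimicrobial Consumption from National Import Records
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for national tier-1 (import-level) surveillance of
    antimicrobial consumption in food animals. Converts finished-product
    import records (injectable liquids, tablet blisters, and
    IU-denominated penicillin formulations) to kilograms of active
    ingredient, estimates a food-animal biomass denominator from census
    interpolation and slaughter statistics, standardises consumption as
    mg of active ingredient per kg of biomass, classifies quantities by
    WOAH veterinary importance and WHO human-health importance, and
    tests annual series for monotonic trend with a from-scratch
    Mann-Kendall test (exact small-sample and normal-approximation
    p-values). Includes a synthetic-data generator with an exact
    ground-truth ledger so every pipeline stage is testable without
    access to confidential import databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    readr,
    rlang,
    yaml,
    jsonlite,
    ggplot2,
    stats,
    utils
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
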