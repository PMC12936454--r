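Package: agrocycle
Title: Circularity Scenarios for Crop-Livestock Systems: Greenhouse-Gas Budgets,
    Drought Classification and Ecosystem-Service Indicators
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates and compares farm-level circularity scenarios
    (business-as-usual, vegan and integrated crop-livestock rotations) under
    historical and warmed climates. Provides a seeded synthetic generator that
    emulates soil-crop-model outputs (daily weather, crop yields, nitrogen
    fluxes, soil organic carbon change), farm-gate greenhouse-gas budgets under
    GWP100 and GWP* accounting, SPEI-3 drought indexing with quantile-based
    extreme-event classification, productivity/stability/resistance statistics,
    nitrate-leaching aggregation, a randomized-search diet supply-demand
    optimizer, and multi-criteria scenario comparison with Kruskal-Wallis and
    Dunn post-hoc tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
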