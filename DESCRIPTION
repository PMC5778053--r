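Package: tidemarsh
Title: Simulating and Validating Coastal Wetland Response to Sea-Level Rise
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Raster simulation of intertidal wetland vegetation change under
    sea-level rise in barrier estuaries, with subsite tidal attenuation and
    three interchangeable surface-elevation-change engines: a SLAMM-style
    class-rate engine with ordered succession rules, an exponential
    elevation-and-channel-distance accretion model, and a linear covariate
    (rainfall, water level, SOI, mean sea level) elevation model. Includes the
    model-evaluation toolkit the engines are meant to be judged with:
    retrospective validation by datum back-stepping, percent-area-difference
    and map-overlap agreement statistics with a 10 percent validity rule,
    one-at-a-time sensitivity analysis, cross-engine comparison, and a seeded
    synthetic barrier-estuary generator so every stage runs without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
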