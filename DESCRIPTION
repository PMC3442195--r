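Package: ctcfields
Title: Green's-Function Simulation of Procoagulant Concentration Fields
    from Circulating Tumor Cells
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Closed-form simulation of thrombin / tissue-factor concentration
    fields emitted by circulating tumor cells (CTCs) diffusing and advecting
    above a vessel wall. Implements the half-plane (2D, no flow) and
    half-space (3D, constant flow) point-source Green's functions with
    method-of-images no-flux walls, linear superposition over arbitrary
    source sets, seeded random source placement, passive six-neighbour
    gradient-tracker diagnostics, run orchestration with slice profiles,
    peak-concentration time series, two-regime decay fits and
    source-count scaling summaries, and an independent explicit
    finite-difference advection-diffusion solver used as a validation
    oracle. All quantities are dimensionless.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
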