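Package: gemflux
Title: Aerodynamic Gradient Fluxes of Gaseous Elemental Mercury over Forests
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Processes tower-based two-height trace-gas concentration
    gradients and micrometeorology into half-hourly gaseous elemental
    mercury (GEM) and CO2 fluxes with the stability-corrected aerodynamic
    gradient method. Includes the full inference chain used for forest
    mercury deposition studies: trap-wise averaging of analyzer samples,
    stability and robust outlier screening, month-by-hour median gap
    filling, canopy/forest-floor and day/night flux partitioning,
    cumulative annual sums, daily-differencing random-error estimation
    with Monte-Carlo confidence intervals, Hg:C uptake ratios, and a
    deposition mass-balance calculator. A synthetic-scenario generator
    inverts the gradient equation so every stage can be exercised against
    known truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    lubridate,
    purrr,
    readr,
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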