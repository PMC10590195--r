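Package: trawlmetrics
Title: Standardized Metrics, Effort Maps and Data Products for Bottom-Trawl
    Fisheries Monitoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computation chain for bottom-trawl fisheries monitoring data:
    parsing haul GPS tracks and computing swept area, length-weight
    relationship fitting, swept-area standardization of abundance (by length
    class) and biomass (by catch category), quality-control validation of
    survey records, a vessel monitoring system (VMS) pipeline that classifies
    fishing activity, fuses daily landings and rasterizes effort, landings and
    revenue maps, a seeded synthetic survey and fleet generator, and exporters
    for length-frequency series, hierarchical catch-composition trees and
    per-haul geolocation documents.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    ggplot2,
    jsonlite,
    xml2,
    geosphere,
    mgcv,
    lubridate,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
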