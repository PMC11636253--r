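Package: aqequity
Title: County-Level Air Quality, Exposure Disparity, and Mortality Impacts of
    Decarbonization Scenarios
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A coupled simulation pipeline that translates multi-sector
    climate-policy emission scenarios into county-level fine-particle (PM2.5)
    exposure, racial exposure disparities, and premature-mortality estimates.
    Regional NOx, SO2 and primary PM2.5 emission trajectories for six stylized
    policy scenarios (current policy, clean electricity standard, carbon tax,
    ICE vehicle ban, ICE ban plus CES, and a 2050 net-zero pathway) are
    downscaled to counties with constant unit generation shares, a
    grow-in-place siting heuristic for new capacity, and vehicle-miles-traveled
    spatial surrogates. A reduced-complexity Gaussian-plume source-receptor
    model with simplified ammonium-nitrate-sulfate partitioning converts county
    emissions to annual-average PM2.5-equivalent concentrations; a log-linear
    concentration-response function converts concentration changes to expected
    deaths by race-ethnicity and age. Includes a synthetic-data module that
    emulates the structure of the real inputs (geography, SSP2-like population
    projections, generating-unit fleets, VMT surrogates) so the full pipeline
    can be exercised, tested, and benchmarked at desk scale.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
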