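Package: rzpawhc
Title: Rootable Depth and Root Zone Plant-Available Water Capacity of Soil Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Evaluates tabular or gridded soil-profile data for maize root zone
    depth (RZD) and root zone plant-available water holding capacity
    (RZ-PAWHC). Water retention at field capacity and wilting point is
    estimated per depth interval with a van Genuchten pedotransfer function
    for tropical soils; piecewise-linear rootability-index rules score the
    adequacy of porosity, soil volume, texture, induration, acidity,
    alkalinity, salinity, sodicity and aluminium toxicity; profile-level
    limits (depth of aeration from drainage class, depth to bedrock, crop
    maximum) and the per-factor restriction depths are combined into the
    rootable depth, and plant-available water is aggregated over it into a
    single capacity in mm. Includes a seeded synthetic-profile generator,
    readers and writers for profile tables and plain-text raster stacks, and
    diagnostics that decompose the capacity into its limiting components.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
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
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
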