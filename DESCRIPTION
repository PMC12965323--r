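Package: multicropr
Title: Multiple-Cropping Expansion Potential Under Irrigation Water Constraints
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Gridded land-water analysis pipeline estimating the potential to
    expand multiple cropping (more than one harvest per year) on existing
    cropland. Classifies cells as suitable for multiple cropping from monthly
    grass gross primary productivity under rainfed and irrigated conditions,
    scales main-season crop yields to off-season yields via grass-productivity
    ratios, computes consumptive irrigation water requirements and withdrawals
    under irrigation-system efficiencies, allocates limited river water along
    an upstream-downstream network with priority users and a 100 km access
    radius, and accounts areas, production and water use for a reference state
    and for expansion scenarios with and without local water limits. Includes
    a seed-reproducible synthetic-world generator emulating the statistical
    structure of gridded crop-model inputs so the full pipeline runs
    self-contained.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    purrr,
    readr,
    rlang,
    stats,
    utils,
    geosphere,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
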