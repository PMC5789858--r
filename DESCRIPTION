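Package: frostphen
Title: Growing-Season Frost Exposure from Satellite Phenology and Gridded Minimum Temperature
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools to quantify vegetation exposure to frost during the growing
    season. Extracts start- and end-of-season dates from bimonthly NDVI
    composites with four curve-fitting methods (harmonic analysis, sixth-order
    polynomial, double logistic, piecewise logistic) and a climatological
    threshold scheme; counts days with minimum air temperature below 0 degrees
    Celsius inside per-pixel phenological windows, split at the summer
    solstice into spring and autumn; maps decadal changes with per-pixel
    Welch t-tests and area-weighted summaries; attributes frost-day changes
    to phenology versus temperature with factorial fixed-driver scenarios;
    and measures local association with moving-window partial correlations.
    Includes a synthetic-earth generator with known phenological and thermal
    truth so the full pipeline is testable without satellite archives, plus
    site-level (leaf unfolding to senescence) frost accounting for network
    phenology records.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    minpack.lm,
    jsonlite,
    yaml,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
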