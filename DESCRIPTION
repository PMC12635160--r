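Package: floodequity
Title: Sea-Level-Rise Flood Hazard and Exposure Equity Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for assessing which neighborhoods bear the burden of
    coastal hazardous sites threatened by sea-level-rise (SLR) driven
    flooding. Computes per-site annual flood exceedance probabilities by
    integrating Poisson-generalized-Pareto flood return curves over
    probabilistic local SLR sample distributions, classifies at-risk sites,
    cleans and geoprocesses raw site registries (categorization, fuzzy-address
    deduplication, parcel and buffer footprints, overlap resolution,
    coastline clipping), assigns block-group exposure outcomes (exposed flag,
    at-risk site count, expected annual exposure) via proximity to populated
    areas, and quantifies exposure disparities with county fixed-effects
    regressions under cluster-robust errors and with concentration curves and
    indices. Ships a deterministic synthetic coastal-region generator so the
    whole pipeline is testable end to end without external data.
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
    MASS,
    purrr,
    rlang,
    sandwich,
    sp,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
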