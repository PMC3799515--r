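Package: rcmcmap
Title: Restricted and Controlled Monte Carlo Disease Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Disaggregates polygon-level aggregate case and cohort counts to
    raster pixels by a population-weighted restricted and controlled Monte
    Carlo (RCMC) allocation, estimates a disease-intensity surface with
    case-side adaptive-bandwidth kernel ratio estimation and indirect
    standardization across demographic strata, attaches Monte Carlo rank
    p-values per cell, and quantifies aggregation-induced spatial uncertainty
    by repeating the disaggregation, ending in mean-p, SD-p and hot-spot
    rasters. Includes a synthetic-geography generator (Voronoi towns,
    settlement-blob background rasters, binomial counts with an optional
    planted elevated-risk cluster) so the full pipeline is testable without
    confidential registry data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    rlang,
    readr,
    generics,
    jsonlite,
    ggplot2,
    mgcv,
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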