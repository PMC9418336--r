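Package: smallfield
Title: Mapping Active Cropland and Short-Term Fallows from Monthly Image Mosaics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mapping active cropland and short-term fallows in
    fragmented smallholder landscapes from monthly multispectral image
    mosaics. Implements multi-temporal coregistration of monthly mosaics
    against seasonal near-infrared reference composites (multi-scale
    block cross-correlation "rubber-sheeting"), a time-series noise
    statistic quantifying multi-temporal consistency, seasonal
    percentile/texture/contrast feature engineering, margin-driven
    active learning around a random-forest classifier, design-based
    stratified accuracy assessment with unbiased (error-adjusted) area
    estimation, and grid-cell aggregation of cropland and fallow
    fractions. A seeded synthetic-landscape generator with known class
    maps, phenology, displacement and clouds makes every stage testable
    without satellite data access.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    jsonlite,
    stats,
    utils,
    generics
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
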