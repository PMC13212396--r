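Package: hepanorm
Title: Pediatric Liver-Size Reference Ranges from BCPE Centile Curves
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds age- and height-based reference centile curves for
    pediatric liver length measured on ultrasound. Provides a complete,
    reproducible pipeline: parsing of free-text measurement reports,
    age-windowed matching of height observations, diagnosis- and
    laboratory-based exclusions, robust two-step outlier screening (hard
    physical bounds, then MAD z-scores and Tukey fences within age and
    height strata), a Box-Cox Power Exponential (BCPE) distribution engine,
    GAMLSS-type distributional regression with penalized B-spline smooths
    for location, scale and skewness and a constant tail-heaviness
    parameter, normalized quantile residual diagnostics, percentile tables
    evaluated at bin midpoints with minimum-count reporting rules, and
    normal/abnormal band classification. A synthetic-cohort generator
    anchored to published centile tables makes every stage testable
    without access to patient data.
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
    graphics,
    jsonlite,
    purrr,
    readr,
    rlang,
    splines,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    optparse,
    patchwork,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
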