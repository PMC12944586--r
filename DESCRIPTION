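Package: vegdrivers
Title: Attribution of Vegetation Change to Natural, Social, Economic and
    Policy Drivers
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for attributing long-term vegetation change (leaf area
    index and similar indices) to natural, social, economic and policy
    drivers over a panel of administrative units. Provides per-series and
    per-cell linear trend estimation with significance classification and
    area-fraction summaries; construction of yearbook-style socioeconomic
    indicators and a land-use-derived Grain-for-Green conversion ratio;
    variance-inflation-factor collinearity screening; a from-scratch
    Geographically and Temporally Weighted Regression (GTWR) with
    spatiotemporal kernel weights and cross-validated bandwidth selection;
    the geographical-detector factor q-statistic with stratification and
    permutation or noncentral-F significance; dominant-factor and
    dimension-averaged attribution summaries; and a synthetic-data module
    that generates panels, trend rasters and land-use stacks with known
    ground truth so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
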