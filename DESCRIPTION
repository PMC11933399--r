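Package: aquahazard
Title: National-Scale Groundwater Quality Hazard Indexing and Population
    Exposure Assessment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for multi-parameter groundwater-quality hazard assessment
    at administrative-district scale. Implements exceedance screening of well
    records against WHO/US EPA and Sri Lanka drinking-water standards, a
    multi-parameter hazard index computed by two estimation pathways
    (ordinary-kriging/IDW spatial interpolation of observed wells, and
    iterative random-forest imputation of incomplete point records), the
    weighted arithmetic water quality index (WAWQI), district-level
    population exposure summaries, and monitoring-station trend analysis
    (monthly aggregation, linear trends, seasonal climatology, mean-ordered
    station heatmap matrices). Because national agency well datasets are
    typically not redistributable, the package ships a synthetic-data
    generator that emulates a realistic well network: Voronoi districts,
    spatially autocorrelated lognormal concentration fields calibrated to
    climate-zone means, configurable per-parameter missingness, and a
    district population surface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deldir,
    jsonlite,
    ranger,
    sp,
    stats,
    utils,
    yaml
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
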