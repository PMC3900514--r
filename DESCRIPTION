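Package: trawlsim
Title: Spatially Explicit Bio-Economic Simulation of Demersal Trawl Fisheries
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Grid-based bio-economic modelling of demersal trawl fisheries.
    Builds spatial layers of survey abundance (inverse-distance-weighted
    interpolation of stratified-random hauls), decomposes length-frequency
    distributions into normal cohort components by EM, maps vessel-monitoring
    pings to per-cell fishing effort via track interpolation and speed
    filtering, forecasts next-year cohort abundances with an Elman recurrent
    network, converts effort patterns into catches, revenues, fuel costs and
    gains with classic fishery-science equations (logistic trawl selectivity,
    spatially partitioned fishing mortality), and explores effort-management
    scenarios (global effort scaling, nursery-box closures) by stochastic
    gain-maximising simulation. Includes a synthetic-data generator with
    retained ground truth so the whole pipeline is testable end-to-end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
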