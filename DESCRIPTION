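Package: bvocanom
Title: Attribution of Long-Term Anomalies in Biogenic VOC Emissions
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to attribute long-term anomalies in biogenic volatile
    organic compound (BVOC) emissions to their principal drivers: vegetation
    biomass (via NDVI regression models per plant functional type), the
    exponential temperature response, the CO2-isoprene inhibition effect,
    soil moisture, and wildfire burnt biomass.  Per-driver fractional
    contributions are combined with a biomass-environment interaction term
    and simple error-margin bookkeeping into annual anomaly series relative
    to a reference year.  Includes seasonal-amplitude analysis, per-pixel
    anomaly mapping with atmospheric-mixing smoothing, historical backcasts
    and scenario projections driven by temperature and CO2 trajectories, a
    synthetic driver-data generator with known ground truth, and a small
    command-line pipeline around plain-text interchange formats.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    digest
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
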