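Package: calciphile
Title: Soil-Niche Analysis of Herbarium Specimen Records and Lime-Tolerance
    Prediction
Version: 0.1.0
Authors@R:
    person("ILVO", "Applied Genetics", role = c("aut", "cre"),
           email = "maintainer@example.org")
Description: Links georeferenced plant occurrence records (e.g. herbarium
    specimens) to a gridded soil database, summarizes soil pH and calcium
    carbonate distributions per grid cell, specimen and taxon, predicts
    lime-tolerant taxa with an upper-quartile threshold rule, and validates
    the prediction with a Yates-corrected chi-square contingency test.
    Includes a synthetic-data generator that emulates the structure of a
    mapping-unit soil raster with linked attribute records, a gazetteer-based
    geocoder with Vincenty-distance accuracy assessment, quartic-kernel
    density surfaces for occurrence mapping, and a reproducible end-to-end
    pipeline with plain-text intermediates.
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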