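Package: traveldelay
Title: Travel-Time Modelling and Delay Analysis for Emergency Obstetric Care Access
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models least-cost travel times to an emergency-care facility over a
    friction raster built from road classes, land cover and slope; calibrates a
    slope friction coefficient against reference drive times; decomposes each
    patient's reported travel time into a modelled best-case time plus a delay;
    and explains delays with rank-based descriptive tables and a
    forward-selection log-linear regression reported as adjusted ratios.
    Includes a synthetic-data module that generates landscapes and survey
    cohorts with known ground truth so the whole pipeline is testable without
    external geodata.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    graphics,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
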