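Package: redscore
Title: Historical Redlining Exposure Scores and Firearm-Injury Rate Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Links graded historical mortgage-security ("redlining") maps to
    modern zip-code zones by polygon overlay, computes an area-weighted
    redlining exposure score on the 1-4 grade scale, tabulates firearm
    injuries from ICD-10 external-cause codes, and fits negative-binomial
    rate models with log-population offsets to estimate incidence rate
    ratios. Includes a planar geometry engine for intersection areas with a
    Monte-Carlo validation oracle, a synthetic-city generator for
    end-to-end testing, the published 36-zone Baltimore dataset as a
    fixture, and a pipeline driver with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
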