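Package: plategazer
Title: Population Movement Analysis of C. elegans Healthspan from Time-Lapse Plate Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Desk-scale implementation of an automated worm-movement ageing
    assay. Detects moving nematodes in time-lapse image stacks of agar plates
    by temporal background subtraction, measures per-object motion-smear
    lengths and speeds, converts object lists into population healthspan
    metrics (fraction of animals moving, mean speed of moving worms, mean
    speed of all worms), aggregates them into condition-level time series
    with per-dish standard errors and area-under-the-curve endpoints, and
    compares conditions with Gaussian-error one-sided significance tests.
    Includes a synthetic plate simulator with exact ground truth for
    validating the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tiff,
    png,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
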