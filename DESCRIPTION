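Package: crowdmap
Title: Visual Crowding, Uncrowded Letter Counts, and Cortical Map
    Conservation
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Links psychophysical visual crowding to the size of
    retinotopic cortical maps. Converts spacing thresholds to Bouma
    factors, computes the number of letters that fit in the uncrowded
    visual field from the Bouma law, fits the cortical-conservation
    model (letter count proportional to map surface area) by regression
    through the origin, and derives the cortical crowding distance with
    bootstrap confidence intervals. Includes a synthetic-observer cohort
    generator and a trial-level QUEST adaptive staircase simulator so
    the full pipeline can be exercised and validated without any
    experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    jsonlite,
    stats,
    utils
Suggests:
    knitr,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
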