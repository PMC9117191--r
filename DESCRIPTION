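Package: burrowscape
Title: Spatial Avoidance Analysis for Burrowing Mammals from Field Plots and Aerial Imagery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to test for spatial avoidance between two burrowing mammal
    species (a colonial ground squirrel and the European mole) from zone-based
    presence/absence plot surveys and remotely sensed mound maps. Implements
    fixed-radius kernel density 95% isopleth range delineation, spacing-
    constrained random plot sampling in survey zones, binomial zone models with
    AUC evaluation and unadjusted (LSD) pairwise contrasts, bounding-box
    detection evaluation (IoU matching, precision/recall/F1/average precision)
    with a classical blob-detector baseline, habitat and transect survey-effort
    accounting, and a synthetic-landscape generator with a tunable avoidance
    parameter so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    stats,
    mgcv,
    jsonlite,
    yaml,
    tiff,
    EBImage,
    ggplot2,
    generics,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
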