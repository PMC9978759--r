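Package: screeNiche
Title: Micro-Topographic Habitat Analysis for Narrow-Endemic Scree Plants
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for testing whether fine-scale terrain shapes the
    distribution of narrowly endemic plants of mountain screes. Computes six
    3x3-neighbourhood topographic predictors (terrain ruggedness index,
    topographic position index, roughness, Horn slope and aspect, and D8 flow
    direction) from a projected digital elevation model; extracts predictor
    values at surveyed presence/absence points; applies a balanced resampling
    significance test suited to strongly unbalanced survey data (e.g. 7
    presences vs 37 absences), comparing the presence mean of each predictor
    with a percentile confidence interval of resampled means; and derives an
    IUCN criterion-B2 threat assessment (area of occupancy, extent of
    occurrence, location count, category). A seeded synthetic-landscape
    generator (Gaussian random field relief plus occurrence placement driven
    by a chosen predictor) makes every stage testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    tools,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
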