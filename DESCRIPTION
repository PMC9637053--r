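Package: fatmapr
Title: Radial Fat-Mapping of Paraspinal Muscle Fat Infiltration with 1D
    Statistical Parametric Mapping
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies the spatial distribution of fat infiltration (FI)
    within paraspinal muscles from water-fat MRI. Builds radial fat-maps:
    mean FI per one-pixel annulus around the L4L5 center of rotation,
    smoothed with a three-point moving average and distance-normalized to
    0-100 percent of the radial muscle width. Compares groups node-wise
    with one-dimensional statistical parametric mapping (two-sample t
    fields, random-field-theory critical thresholds, cluster-level
    inference), summarises curve peaks and their deep/intermediate/
    superficial location, and orchestrates cohort analyses stratified by
    symptoms and disc pathology. Includes a synthetic phantom generator
    with closed-form ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    png,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
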