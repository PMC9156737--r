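Package: pollenclim
Title: Pollen-Based Precipitation Reconstruction with Scale-Space
    Significance Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantitative reconstruction of past precipitation from fossil
    pollen assemblages. Implements the Weighted Averaging-Partial Least
    Squares (WA-PLS) transfer function with leave-one-out cross-validation
    and the usual calibration diagnostics (R2, RMSEP, maximum bias,
    variance inflation factors), analogue quality control based on
    squared-chord dissimilarities, and SnSiZer: a SiZer-style scale-space
    significance map whose feature magnitudes are scale-normalized
    derivatives of a Nadaraya-Watson smooth, so that the strength of
    climatic shifts can be compared across smoothing levels. A seeded
    generator for unimodal taxon-climate responses, modern calibration
    sets and irregular fossil records allows the whole chain to be
    exercised and validated without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
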