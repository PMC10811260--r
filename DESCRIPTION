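Package: trifield
Title: Drought Phenotyping Analysis for Two-Field Forage Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of paired control/rain-out-shelter field
    trials of forage crop accession panels phenotyped by UAV. Builds and
    validates incomplete block designs, extracts plot-level traits (canopy
    cover, Q90 canopy height, crop water stress index, cumulative water
    deficit), filters faulty plots, fits intercept-plus-random-effects
    variance component models with AIC model selection to produce accession
    BLUPs and broad-sense heritability, computes relative drought performance
    indices (Yr) with Z-tests, and runs multivariate structure and
    top-quartile overlap analyses. Includes a synthetic trial generator with
    known ground truth for validation and power studies.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    lme4,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
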