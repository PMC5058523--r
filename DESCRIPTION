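Package: invasim
Title: Invasion Risk Modeling with Presence-Background Suitability and
    Dispersal-Constrained Projections
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for assessing invasion risk of range-expanding species
    into cultivated landscapes: collinearity screening of environmental
    predictor rasters, a presence-background maximum-entropy habitat
    suitability model with replicate evaluation (AUC, true skill statistic,
    maximum sensitivity-plus-specificity thresholding), variable-importance
    diagnostics, habitat-overlap statistics, a three-component invasion-risk
    score, and a MIGCLIM-style cellular-automaton dispersal simulation over
    future environmental series. Includes a synthetic-landscape generator
    with known ground truth for end-to-end validation, and a lightweight
    raster data model with Esri ASCII grid input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
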