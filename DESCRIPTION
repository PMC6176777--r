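Package: canophen
Title: Plot-Level Crop Phenotyping from Multiband Aerial Imagery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for extracting plot-level morphological and spectral
    traits from multiband reflectance orthomosaics and digital surface
    models of field trials, and for relating those traits to biomass,
    leaf nitrogen and chlorophyll. Includes shadow-aware sunlit-vegetation
    segmentation by excess-green thresholding, canopy height models from
    DSM minus interpolated terrain, per-plot height percentiles, canopy
    cover and eight vegetation indices, exponential (log-linear) biomass
    regression with k-fold cross-validation and predictor admissibility
    screening, and a synthetic field-scene generator with known ground
    truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    tibble,
    jsonlite,
    yaml,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
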