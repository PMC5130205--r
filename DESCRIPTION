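Package: bonexs
Title: Long Bone Cross-Sectional Geometry and Comparative Allometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes cross-sectional geometric properties of long-bone
    diaphyses and femoral necks from segmented CT section images (areas,
    second moments of area, true section moduli, principal axes), measures
    superior and inferior femoral-neck cortical thicknesses, and positions
    individual specimens against comparative samples using reduced major
    axis (RMA) allometry on log10 scale, with prediction intervals,
    deviations expressed in standard-error-of-estimate (SEE) units, the
    nonparametric Quick Test for elevation differences, permutation tests
    for slope equality, bilateral-asymmetry scoring, and conversions among
    structural properties and section locations. Includes a synthetic-data
    generator producing rasterized hollow-ellipse sections with analytic
    ground truth and comparative bivariate samples with known allometric
    structure.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    png,
    tiff,
    stats,
    utils,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
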