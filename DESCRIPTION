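Package: hemochroma
Title: Colorimetric Plasma Free Hemoglobin and Hematocrit from Centrifuged
    Channel Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Image-based hematology for point-of-care hemolysis monitoring
    during mechanical circulatory support. From an 8-bit RGB image of a
    centrifuged micro-channel the package measures plasma free hemoglobin
    (PFHb) through a CIELab chroma difference between a black reference
    marker and the plasma band, corrected for illumination drift and mapped
    through a two-segment standard curve, and measures hematocrit and
    hemoglobin from the packed-cell column geometry. Includes a synthetic
    cartridge-image simulator with ground-truth labels, calibration fitting
    with limit-of-detection estimation, hemolysis staging, and the
    method-comparison statistics (ordinary least squares regression,
    Bland-Altman limits of agreement, replicate precision) used to validate
    such devices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    withr
Suggests:
    farver,
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
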