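Package: wingplan
Title: Folded-Wing Estimation of Avian Wing Area and Aspect Ratio
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates the total wing area and aspect ratio of birds from
    three linear measurements of museum study skins (wingspan, wing length,
    and wing width) using closed-form geometric planform models (triangle,
    ellipse, ellipse-triangle, and a continuous ellipse-fraction mixture).
    Also implements the traditional spread-wing workflow (binary image
    segmentation, scaled area measurement, and root-box reconstruction),
    method-comparison statistics (log10 discrepancy, percent differences,
    coefficients of variation), and phylogenetic generalized least squares
    with a Pagel's lambda correlation structure, regression through the
    origin, and AICc. Ships ground-truth synthetic planform, raster, and
    phylogenetic trait generators for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    ape,
    EBImage,
    jsonlite,
    MASS,
    stats,
    utils
Suggests:
    nlme,
    optparse,
    png,
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
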