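Package: forestfrag
Title: Fractal Fragmentation, Connectivity and Lacunarity Analysis of
    Forest-Cover Change Rasters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Particle (patch) statistics and fractal indicators for binary
    forest-cover rasters: box-counting dimensions and the Fractal
    Fragmentation Index (FFI), the per-pixel Local Connected Fractal
    Dimension (LCFD), and fixed-grid lacunarity with an optional randomized
    Tug-of-War second-moment sketch.  Includes a seeded synthetic
    forest-change generator emulating a three-layer tree-cover / loss-year /
    gain raster stack with recorded ground truth, and a yearly time-series
    pipeline with min-max standardization and Spearman rank correlation
    reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    tiff,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    EBImage,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
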