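Package: phenoleaf
Title: Multispectral Leaf Image Processing for Touch-Based Plant Phenotyping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Processing chain for four-band (blue, green, red, near-infrared)
    leaf images acquired by touch-based proximal phenotyping devices that hold
    the leaf against a fine nylon-thread grid. Provides white-reference
    flat-field calibration, Greenness-based leaf segmentation with
    morphological refinement, Gabor-filter detection of the thread grid,
    exemplar-based (patch-copy) inpainting of the occluded pixels, whole-leaf
    NDVI extraction, and the treatment-separation statistics (two-sample
    t-tests, ordinary least squares) used to relate the index to nitrogen
    status. A synthetic-scene generator with full ground truth supports
    end-to-end validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
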