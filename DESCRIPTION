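Package: cfoselect
Title: Coarse-Fine-Optimal Wavelength Selection for Hyperspectral Leaf
    Trait Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Three-stage ("coarse-fine-optimal") characteristic wavelength
    selection for visible/near-infrared hyperspectral chemometrics, with
    partial least squares regression (PLSR) modelling of leaf nitrogen and
    chlorophyll content and pixel-wise trait inversion mapping. Provides
    interval-level coarse selectors (interval random frog style "iRF" and
    iVISSA), model-population fine selectors (CARS, BOSS, VCPA), final
    refinement by IRIV and a genetic algorithm, SPXY calibration/prediction
    partitioning, Savitzky-Golay/SNV/detrending preprocessing, ENVI cube
    input/output with radiometric calibration, an enhanced Lee speckle
    filter and pseudocolor concentration maps, plus a synthetic leaf
    reflectance generator so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    grDevices,
    jsonlite,
    png,
    Rcpp,
    signal,
    stats,
    tiff,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
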