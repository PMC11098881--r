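Package: ultrasim
Title: Ray-Traced Ultrasound Simulation from Tissue Labelmaps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Physics-based ray-traced B-mode ultrasound simulation over integer
    tissue labelmaps, including a speckle-free intermediate-representation (IR)
    preset that renders tissue interfaces only. Ships a synthetic abdominal
    phantom generator with abdominal aortic aneurysm (AAA) synthesis via
    thin-plate-spline deformation under a rigid spine constraint, alternative
    intermediate representations (edge maps, speckled simulation) for
    comparison, and a compact U-Net aorta segmenter with Dice and
    anterior-posterior diameter evaluation against the clinical 8 mm
    acceptability bound.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    generics,
    graphics,
    grDevices,
    jsonlite,
    png,
    Rcpp,
    RNifti,
    stats,
    tibble,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
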