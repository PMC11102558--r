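Package: ajdisc
Title: Quantification of Adherens Junction Discontinuity in Endothelial
    Monolayer Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify the integrity of endothelial adherens
    junctions from single-channel cadherin-5 (VE-cadherin)
    immunofluorescence micrographs. A fixed, fully recorded operator chain
    (rolling-ball background subtraction, double Gaussian blur,
    sharpening, Huang fuzzy auto-thresholding, binary dilation, endpoint
    bridging and skeletonization) traces closed single-cell outlines from
    the junction network; the per-cell ratio of junction discontinuity is
    then read from a fixed-threshold binary junction mask as the
    percentage of outline pixels with no above-threshold signal.
    Condition groups are compared with the Kruskal-Wallis rank test, and
    transendothelial electrical resistance (TEER) readings are
    blank-corrected and area-normalized. A synthetic monolayer image
    generator with known junction geometry and controllable gap fractions
    provides ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    grDevices,
    graphics,
    jsonlite,
    Rcpp,
    stats,
    tiff,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
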