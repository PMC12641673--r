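Package: macrovol
Title: Volumetric Macrophage Segmentation and Morphometry for Light-Sheet Stacks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: ROI-masked 3D segmentation and morphometric quantification of
    macrophage marker channels in cleared-tissue light-sheet image stacks.
    Provides anatomically masked thresholding, 26-connectivity object
    labeling with small-object and volume-outlier filtering, per-cell
    morphometrics (physical volume, rasterized convex-hull solidity,
    equivalent-sphere radius), solidity-based ameboid/ramified
    classification, per-region summaries and ROI occupancy, voxel-wise
    multi-rater Fleiss kappa, and a synthetic phantom generator with exact
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo: Rcpp
Imports:
    Rcpp,
    RNifti,
    tiff,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
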