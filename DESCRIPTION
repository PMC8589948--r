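Package: spineseg
Title: Two-Stage Vertebra Localization and Segmentation for Spine CT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Instance segmentation of vertebrae in computed tomography.
    Stage one localizes vertebra centroids on transversal slices by
    regressing a dense centroid-proximity encoding with a 2D Dense-U-Net
    and decoding it with a Savitzky-Golay-smoothed slice-maximum profile,
    peak detection, and least-squares circle fitting.  Stage two segments
    each vertebra inside a fixed-size region of interest anchored at its
    centroid with a 3D Dense-U-Net, then thresholds, filters small
    components, and merges the instances into a labeled spine at native
    resolution.  Includes MetaImage (mhd/raw) input/output, isotropic
    resampling, a synthetic spine-phantom generator with ground-truth
    masks and centroids, elastic-deformation and noise augmentation, and
    localization and segmentation metrics (location error, detection
    rate, Dice, IoU, Hausdorff distance, pixel accuracy).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    signal,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
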