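Package: renalwsi
Title: Whole-Slide Renal Biopsy Segmentation, Fusion and Morphometry
Version: 0.1.0
Authors@R:
    person("renalwsi", "developers", email = "renalwsi@example.org",
           role = c("aut", "cre"))
Description: A testable re-implementation of a whole-slide image (WSI)
    analysis pipeline for paediatric renal biopsies. Generates paired
    pseudo-histology slides (H&E at 10x and 40x, PAS at 40x) with exhaustive
    ground truth, tiles slides with Otsu foreground gating and exact
    invertible patch transforms, runs pluggable instance-segmentation
    backends per patch (a deterministic colour-and-shape reference backend is
    included), fuses patch detections into whole-slide results via per-class
    non-maximum suppression and cross-magnification coordinate transforms,
    classifies glomeruli as crescentic or non-crescentic, quantifies
    morphometry and mesangial/endocapillary hypercellularity, and evaluates
    detections with PASCAL VOC 11-point average precision, ROC/AUC, Spearman
    correlation, intraclass correlation and ANOVA with Tukey post hoc tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
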