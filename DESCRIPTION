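Package: prosegvar
Title: Variability Analysis of Manual and Semi-Automatic 3D Prostate Surface Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying inter- and intra-observer variability of
    manual and semi-automatic prostate segmentation on 3D transrectal
    ultrasound geometry. Provides triangle-mesh and sparse point-annotation
    data structures with PLY/STL/OBJ and CSV/JSON input and output, surface
    comparison metrics (average surface distance, volumetric Dice on a
    common voxelization, Hausdorff distance), statistical shape model
    construction and strict-subspace fitting to sparse expert points, a
    B-spline regularized deformable ("soft") shape-model fit, a STAPLE-like
    expectation-maximization mesh consensus, effect-size statistics from
    median/IQR summaries (Cohen's d with sigma approximated by IQR/1.35),
    spatial point-density and variability surface maps, a synthetic
    multi-expert cohort generator, and an orchestration layer that runs the
    complete variability study and emits summary tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
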