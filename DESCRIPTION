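Package: menisq
Title: Quantitative 3D Meniscus Morphometry and Structural Progression Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes quantitative three-dimensional measures of meniscus
    position (extrusion distance, extrusion area, tibial plateau coverage)
    and morphology (volume, height, width) from voxelized coronal
    segmentations of a femorotibial compartment, including central-slice
    surrogate measures. Classifies knees as structural progressors or
    non-progressors using smallest-detectable-change (SDC) thresholds on
    longitudinal cartilage thickness and minimum joint space width, builds
    caliper-constrained 1:1 matched case-control sets, and summarises
    matched comparisons with paired t-tests, 95% confidence intervals and
    Cohen's D effect sizes, plus entire-versus-central-slice correlation
    analyses. Ships synthetic voxel phantoms with analytic ground truth and
    a cohort simulator so the full pipeline can be exercised without
    clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    MASS,
    RNifti,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
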