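Package: quadratvol
Title: Vegetation Volume and Biomass Allometry from Photo-Quadrat Point Clouds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates above-ground vegetation volume and biomass from dense
    Structure-from-Motion point clouds of small (0.4 m x 0.5 m) quadrat sampling
    frames in grass- and litter-dominated rangelands. Implements statistical
    outlier denoising, ground/vegetation classification by a simple
    morphological filter (SMRF) followed by iterative Gaussian-mixture
    refinement on local surface curvature, triangulated terrain surface
    fitting, and three volumetric estimators (canopy height model, 3-D convex
    hull, and voxel occupancy across edge lengths), together with the
    volume-to-biomass allometric regressions, effect-size power screening,
    Wilcoxon voxel-size comparisons, and agreement statistics (total least
    squares, Lin's concordance). A parametric synthetic-scene generator with
    exact per-point labels and reference surfaces supports validation of every
    stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    FNN,
    interp,
    stats,
    utils,
    tools,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
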