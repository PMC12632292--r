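Package: subplate
Title: Regional Morphometry and Growth Analysis of the Fetal Subplate
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Surface-based and volumetric morphometry of the transient fetal
    subplate compartment (thickness, surface area, volume, and depth from
    corresponded inner/outer triangle-mesh pairs and label volumes), robust
    covariate residualization by RANSAC regression with AIC-selected linear or
    quadratic gestational-age models, trimester growth comparison with
    delta-method confidence intervals, hemispheric asymmetry-index inference
    with Benjamini-Hochberg correction, repeated-measures ANCOVA with partial
    eta squared, and Ward clustering of relative growth-rate trajectories with
    silhouette-based model selection. Includes a synthetic cohort generator
    with closed-form ground truth so every stage of the analysis is testable
    without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    cluster,
    pracma,
    RNifti,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
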