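Package: graftgauge
Title: Stent-Graft Migration Risk from Aneurysm Geometry and Wall Shear Stress
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the spatial configuration of abdominal aortic aneurysms
    (AAA) and bifurcated stent-grafts from triangle surface meshes and estimates
    stent-graft migration risk from hemodynamic drag. Implements
    reference-cylinder shape factors, a pulsatile quasi-1D wall-shear-stress
    surrogate with Quemada shear-thinning blood rheology
    (Rabinowitsch-Mooney inversion), cardiac-cycle WSS aggregation and drag
    forces, a long- versus short-body configuration comparison, CT-angiography
    style image-quality metrics (brightness-to-noise, contrast-to-noise) with
    region-growing segmentation on voxel phantoms, and a deterministic synthetic
    anatomical cohort generator, plus mean +/- SEM, correlation and linear
    regression reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
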