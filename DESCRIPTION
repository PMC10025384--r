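Package: aortamorph
Title: Shape-Based Morphometry and Growth-Risk Classification of the
    Ascending Aorta
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes local shape features of the ascending aorta from a
    segmented luminal surface mesh: the maximum cross-sectional diameter D
    obtained by a rotating-plane sweep over sections perpendicular to the
    lumen centerline, the diameter-centerline ratio DCR, the ratio EILR
    between the lengths of the external and internal curvature lines
    (discrete surface geodesics between the annulus and brachiocephalic
    ostium boundaries), and the centerline tortuosity T. Couples the
    features to aneurysm growth-rate estimation between two exams, risk
    class assignment, rank correlation and group comparison, and a
    six-model leave-one-out cross-validated classification benchmark with
    confusion-matrix metrics, diagnostic likelihood ratios and AUROC. A
    parametric tube generator (cylinders, torus segments, helical tubes,
    Gaussian-bulge aneurysms) with closed-form ground truth supports
    verification without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    igraph,
    MASS,
    class,
    rpart,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'aao-domain.R'
    'aortamorph-package.R'
    'centerline.R'
    'curvature-lines.R'
    'geometry-utils.R'
    'growth.R'
    'mesh-io.R'
    'pipeline.R'
    'sections.R'
    'synthetic.R'
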