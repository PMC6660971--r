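Package: radrep
Title: Reproducibility-Screened CT Radiomics for Small Lung Nodules
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Extracts a 252-feature radiomics panel (histogram, 3D/2D shape,
    sigmoid margin, fractal, GLCM, ISZM, NGTDM, Laplacian-of-Gaussian) from
    segmented lung-CT nodules under perturbed voxel-geometry and
    histogram-binning settings, screens features by two-way absolute-agreement
    intraclass correlation, selects status-explaining signatures with
    cross-validated LASSO and cross-setting intersection, validates signatures
    with a 200-tree random forest, and audits failed texture computations to
    derive minimum-nodule-size guidelines. Includes a seeded synthetic nodule
    generator so the whole pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    tools,
    stats,
    utils,
    glmnet,
    randomForest,
    RNifti,
    withr,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
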