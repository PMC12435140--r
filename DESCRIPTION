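Package: cebconn
Title: Cognition-Eye-Brain Association Analysis for Multimodal Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for studying cognition-eye-brain associations in the
    Alzheimer's disease spectrum from multimodal imaging. Computes
    resting-state fMRI metrics (fractional amplitude of low-frequency
    fluctuations, regional homogeneity via Kendall's coefficient of
    concordance), retinal morphometry from OCTA-derived segmentation
    masks (foveal avascular zone area and perimeter, vessel centerline
    curvature, retinal layer thickness), group-comparison statistics,
    and a two-stage multivariable linear regression linking cognitive
    scores and ophthalmic biometrics to voxel-wise and region-wise
    brain metrics, with permutation-based family-wise error control.
    Includes a synthetic multimodal cohort generator with plantable
    linear effects so the full pipeline can be exercised and calibrated
    without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    Matrix,
    RNifti,
    jsonlite,
    signal,
    png,
    EBImage
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
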