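Package: lfcalcium
Title: Calcium Activity Extraction from Light-Field Microscopy Videos
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for scanless light-field microscopy (LFM) calcium imaging:
    a linear lenslet filter-bank forward model with its exact adjoint,
    model-based volume reconstruction (Richardson-Lucy and sparsity-promoting
    ISTA/FISTA), pixel-wise activity-map preprocessing, 3D Voronoi-Otsu
    segmentation, calcium trace extraction by ROI averaging or by
    pseudoinverse demixing of light-field footprints, trace quality metrics
    (SNR, matching, neighbor crosstalk, downsampling), AR(1) spike
    deconvolution with ensemble clustering, and a synthetic light-field video
    generator with ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    tiff,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    glmnet,
    optparse
Config/testthat/edition: 3
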