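Package: mcseg
Title: Microcalcification Segmentation by Hessian-Constrained Blob
    Detection and Dense Regression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Two-branch segmentation of microcalcifications on digital
    mammograms. A multiscale difference-of-Gaussians blob detector with
    Hessian convexity constraints delineates bright blob-like and tubular
    candidate objects; a fully convolutional dense-regression network,
    trained against exponential proximity maps with a soft Dice loss,
    marks regions where microcalcifications are likely; the two branches
    are fused by an overlap criterion. Includes free-response ROC
    evaluation with bootstrap partial AUC, per-object and per-image
    intersection-over-union metrics, a synthetic mammogram phantom
    generator with mixed point/contour ground truth, and a downstream
    morphology-based malignancy classifier (31 shape and intensity
    features, patient-wise cross-validated gradient boosting).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    igraph,
    jsonlite,
    mgcv,
    png,
    pROC,
    stats,
    tiff,
    utils,
    xgboost
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
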