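Package: dgcn
Title: Annotation-Free Retinal Image Grading with a Deep Graph Correlation Network
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trains an image-grading embedding without manual annotations by
    combining a convolutional encoder, a per-batch K-nearest-neighbor graph,
    degree-normalized graph convolution, and three unsupervised losses
    (graph-center, pseudo-contrastive driven by a shared-neighbor pseudo-label
    estimator, and transform-invariant). Query images are graded by nearest
    match to a small labeled gallery, and the package reports the standard
    screening statistics (sensitivity, specificity, accuracy with Wilson
    confidence intervals, ROC/AUC). Includes a synthetic fundus-like image
    generator with graded lesion load so the full pipeline is testable at desk
    scale, plus a command-line interface for dataset synthesis, training,
    prediction, and evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    png,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
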