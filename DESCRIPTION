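Package: fedlesion
Title: Weakly-Supervised Prostate Lesion Detection with Federated Training Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detection and grading of clinically significant prostate cancer from
    multi-parametric MRI under mixed-granularity histopathology supervision. Provides
    gland-referenced intensity normalization (IQR99 and Z-score) and grid resampling for
    registered T2WI/DWI/ADC volumes; a dynamically-populated multi-task objective that
    dispatches per-region loss terms on a supervision signal (strong lesion biopsies,
    weak systematic or exam-level biopsies) via soft region histograms of a voxel-wise
    grade-group map; a small configurable 3D residual encoder-decoder with a region
    classification head, trained by exact analytic backpropagation; a local simulation of
    federated stochastic gradient descent with server-side AdamW and private per-client
    checkpoint selection; a two-site synthetic phantom generator emulating inter-site
    contrast heterogeneity; and evaluation utilities (lesion IoU, occurrence-normalized
    class-balanced accuracy with TNR/TPR, cross-site comparison tables).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    RNifti,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
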