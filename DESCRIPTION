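Package: gaitkit
Title: Markerless Pathological Gait-Type Classification from 2D Video
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end toolkit for classifying pathological gait types
    (scissor, spastic, steppage, propulsive, normal) from sagittal-view 2D
    video recorded against a chroma-key background. Provides HSV
    histogram-based silhouette segmentation, gait-cycle detection, Gait
    Energy Image (GEI) and Skeleton Energy Image (SEI) representations from
    silhouettes and BODY_25 pose keypoints, a lightweight five-layer
    convolutional neural network classifier trained with Nesterov-Adam,
    subject-wise k-fold cross-validation with confusion-matrix reporting,
    and gradient saliency plus grad-CAM explanations. A procedural
    articulated-walker simulator generates labelled chroma-background
    sequences, ground-truth masks and pose files so the whole pipeline can
    be exercised without any external dataset.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    grDevices,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
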