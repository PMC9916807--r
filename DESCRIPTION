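Package: wsimil
Title: Weakly Supervised Whole-Slide Image Classification with
    Clustering-Constrained Attention Multiple Instance Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Annotation-free classification of whole-slide images from
    slide-level labels only. Implements the full weakly supervised
    pipeline: tissue segmentation and patch tiling, pluggable patch
    encoders, gated attention pooling with class-specific branches,
    an instance-clustering auxiliary objective trained with a smooth
    multi-class SVM loss, Adam-based training with early stopping,
    slide-level evaluation metrics, and attention heatmap rendering.
    Includes synthetic fixture generators (toy slides and Gaussian
    multiple-instance feature bags) so every stage can be exercised
    and validated without real slides.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    data.table,
    jsonlite,
    yaml,
    pROC,
    EBImage,
    tiff,
    png
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
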