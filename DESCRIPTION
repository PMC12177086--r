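Package: axilnet
Title: Two-Stage Multi-Task and Multi-Instance Learning for Axillary
    Lymph Node Status Prediction from Multi-View Ultrasound
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Implements a two-stage deep learning framework for
    predicting axillary lymph node (ALN) metastasis in breast cancer
    from multi-view B-mode ultrasound. Stage one is an image-level
    multi-task network that jointly segments the lesion, classifies the
    lesion type (primary tumor versus lymph node) and predicts
    image-level metastasis status, using the predicted segmentation map
    as an attention gate on the feature maps. Stage two is a
    patient-level multi-instance transformer that pools a variable-size
    bag of per-image tokens through a learnable CLS token. The package
    ships a seeded synthetic speckle-phantom cohort generator with
    ground-truth polygon annotations, LabelMe-dialect annotation I/O,
    config-driven training and inference engines, class activation
    mapping for the pool-then-linear classification heads, and the full
    diagnostic evaluation stack (ROC/AUC, paired DeLong tests,
    precision-recall, decision curve analysis, mean IoU, chi-square
    cohort comparisons and a clinical logistic baseline).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    jsonlite,
    yaml,
    tools,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
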