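Package: piter
Title: Genopathomic Tumor Mutational Burden Biomarker from H&E Slides
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds a patient-level tumor-mutational-burden (TMB) biomarker
    from hematoxylin-eosin stained histology images. Slides are tiled into
    tissue patches, stain-normalized by optical-density (Macenko)
    deconvolution, and scored by a compact convolutional classifier trained
    with adversarial confounder suppression: a gradient-reversed auxiliary
    head classifies the slide of origin so that the learned representation
    becomes invariant to slide-level staining and scanner shortcuts.
    Patch probabilities are aggregated per patient by the median, the
    decision cutoff is chosen by the Youden index, and the score is
    evaluated as a biomarker via ROC/AUC with percentile-bootstrap
    confidence intervals, Spearman association with continuous TMB,
    Kaplan-Meier stratification with a log-rank test, and spatial
    probability heatmaps. A built-in synthetic cohort generator emulates
    TMB-linked nuclear texture and confounded slide-level color shifts so
    the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    grDevices,
    graphics,
    jsonlite,
    nnet,
    png,
    stats,
    utils
Suggests:
    EBImage,
    pROC,
    survival,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
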