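Package: heki67
Title: Predicting Ki67 Positivity from Nuclear Morphometry on H&E Images
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to predict the Ki67/MIB1 immunohistochemical labeling
    status of tumor cells directly from hematoxylin-and-eosin (H&E) stained
    histology images. Implements Beer-Lambert optical-density transform and
    Ruifrok-Johnston color deconvolution, watershed-based nucleus
    segmentation, per-nucleus morphometric and densitometric feature
    extraction (centrally the nuclear hematoxylin mean optical density,
    NHMOD), tumor versus stroma classification with a random-forest and
    comparison classifiers, ROC-based feature ranking and single-cell Ki67
    calling with diagnostic confusion metrics, core-level positivity calls
    under a >10 percent rule, and blue-to-yellow false-color-map rendering.
    A synthetic tissue-microarray core generator with full ground truth
    supports validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    tools,
    EBImage,
    randomForest,
    e1071,
    class,
    png,
    tiff,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
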