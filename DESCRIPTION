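Package: hemlabel
Title: Molecular Label Transfer from IHC to H&E Histopathology Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Transfers molecular (immunohistochemistry-derived) cancer labels
    onto matched hematoxylin-and-eosin whole-slide images. Provides stain
    color normalization to a template slide (Vahadane, Macenko, Reinhard),
    mutual-information image registration (affine followed by B-spline),
    Ruifrok-Johnston color deconvolution with two-stage Otsu thresholding of
    the DAB channel, tile-level cancer/normal/uncertain labeling with
    quality-control filters, a transfer-learning tile classifier with a
    pluggable feature backbone, evaluation metrics, and tissue-area-weighted
    tumor purity estimation. Includes a synthetic paired-slide generator with
    known stain matrices, misalignment and cancer masks so that every
    pipeline stage can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    png,
    tiff,
    jsonlite,
    yaml,
    withr,
    stats,
    utils,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
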