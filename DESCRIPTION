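Package: pneumoseg
Title: Backbone U-Net Segmentation Toolkit for Pneumothorax on Chest Radiographs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tooling for semantic segmentation of pneumothorax in chest
    radiographs: codecs for the relative run-length-encoded (RLE) mask format
    used by the SIIM-ACR challenge, DICOM/PNG ingestion and preprocessing,
    training-time augmentation, four backbone U-Net architectures
    (ResNet-50, DenseNet-169, SE-ResNeXt-50, EfficientNet-B4) with
    nearest-neighbour-upsampling decoders built on a self-contained
    computational-graph engine, BCE-Dice training with cosine annealing and
    terminal checkpoint weight averaging, flip test-time augmentation,
    dual-threshold post-processing with grid search, weighted probability-map
    ensembling, an evaluation metric suite (IoU, confusion metrics, PSNR,
    mean Dice with the competition's empty-mask convention), and a
    deterministic synthetic chest-phantom generator so the whole pipeline is
    exercisable without the competition dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    EBImage,
    png,
    tiff,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
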