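Package: OverlapSynth
Title: Synthesis of Overlapping Nucleus Images for Imbalanced Training Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Synthesizes overlapping-nucleus grayscale images from
    single-nucleus images to rebalance imbalanced cell-image training sets,
    as used in DNA ploidy analysis of Feulgen-stained cervical specimens.
    Source nuclei are chosen by representative sample selection, rotated by
    random angles, segmented by valley-point histogram thresholding, placed
    with a randomly drawn overlap length, and the overlap-region pixels are
    reconstructed by optical-density additivity (Beer-Lambert law).  Also
    provides the accompanying region-morphology and co-occurrence texture
    feature extractor, G-mean based multiclass evaluation, thin adapters
    over standard classifiers, and an experiment harness that sweeps a
    schedule of imbalance ratios on synthetic Feulgen-like fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    grDevices,
    utils,
    EBImage,
    png,
    jsonlite,
    nnet,
    e1071,
    mclust,
    randomForest,
    xgboost,
    class
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: CellBiology, Classification, Preprocessing
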