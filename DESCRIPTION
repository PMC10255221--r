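Package: freshspec
Title: Multi-Mode Spectroscopy Pipeline for Fish Freshness Assessment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation, preprocessing, chemometric exploration,
    classification and decision-level fusion for multi-mode spectral
    assessment of fish-fillet freshness. Generates synthetic fluorescence,
    visible/near-infrared and short-wave-infrared hypercubes with a
    day-dependent aging signal and first-order nucleotide catabolite
    kinetics; converts hypercubes to voxel spectra (white/dark calibration,
    exposure scaling, masking, 10x10 spatial averaging, outlier-voxel
    rejection, SNV and Savitzky-Golay pretreatments); extracts aging
    features (PCA with retention rules, self-organizing maps with
    hierarchical clustering, two-peak fluorescence deconvolution, K/H
    freshness indices, hit-quality spectral matching); trains per-mode
    day classifiers including a stacked ensemble (LR/RF/KNN bases, LDA
    meta-learner on features plus predictions); and fuses the three modes
    by majority vote with a SWIR tie-break, reporting exact, one-day
    tolerance and grade-grouped accuracies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    class,
    nnet,
    rpart,
    randomForest,
    e1071,
    signal,
    minpack.lm,
    EBImage,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    optparse,
    withr
Config/testthat/edition: 3
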