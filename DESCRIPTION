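Package: ermmap
Title: Epiretinal Membrane Detection and En-Face Mapping in Retinal OCT Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fully automatic detection of epiretinal membrane (ERM) presence along
    the inner limiting membrane (ILM) in stacks of 2D OCT B-scans, and rendering of
    an en-face 2D map of ERM extent. Includes a synthetic OCT phantom generator with
    per-pixel ground truth, active-contour (snake) ILM segmentation, a fixed-order
    452-value texture/intensity/domain feature descriptor per ILM point, SURF
    (Spatial Uniform ReliefF) feature ranking, random forest / SVM / k-nearest
    neighbour classification with cross-validated feature-count sweeps, en-face map
    reconstruction, and morphological map refinement with confusion-matrix metrics
    (sensitivity, specificity, Dice, Jaccard).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    png,
    tiff,
    EBImage,
    e1071,
    randomForest,
    class,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
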