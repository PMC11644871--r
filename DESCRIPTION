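Package: claheseg
Title: Modified-CLAHE Enhancement and CNN Segmentation for Kidney CT
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Toolkit for contrast enhancement and segmentation of kidney
    CT slices. Implements contrast-limited adaptive histogram equalization
    (CLAHE) from first principles, selects its tile-count and clip-limit
    parameters per image by minimizing a no-reference image-quality score
    (a BRISQUE-style natural-scene-statistics pipeline) over a parameter
    grid, aggregates per-image selections into dataset-level parameters by
    frequency, trains a small convolutional encoder-decoder to produce
    per-pixel kidney masks, refines masks with binary erosion and
    morphological opening, and evaluates segmentations with Dice, IoU and
    confusion-matrix metrics. Includes a synthetic CT-like phantom
    generator with ground-truth masks, NIfTI/PNG input-output helpers with
    Hounsfield-unit windowing, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
LinkingTo:
    Rcpp
Imports:
    Rcpp,
    png,
    RNifti,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
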