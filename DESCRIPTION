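Package: beadspot
Title: Detection and Counting of Sub-Resolution Fluorescent Beads in
    Low-Resolution Microscopy Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A pipeline for detecting and counting sub-resolution
    fluorescent beads (about 2-4 px in diameter) in single-channel
    low-resolution microscopy images. Images are bilinearly upsampled so
    that touching beads become separable, a compact U-Net is trained on
    small seed labels with a combined binary cross-entropy and Dice loss,
    and predictions are thresholded, labeled and reduced to centroids for
    counting. Includes a synthetic bead-image generator with exact ground
    truth, three classical baseline detectors (Laplacian-of-Gaussian blob
    detection, circular Hough transform, Otsu thresholding with Euclidean
    distance transform), and a detection evaluation scheme reporting
    missing, split and added beads with border correction.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    tiff,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
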