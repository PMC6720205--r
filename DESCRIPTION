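Package: embryogan
Title: Dense Generative Adversarial Networks and Quality Evaluation for
    Synthetic Embryo Microscopy Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Generates synthetic grayscale images of early-cleavage human
    embryos (one-, two- and four-cell stages) with a fully connected
    generative adversarial network trained from scratch, and evaluates
    generated image sets against reference sets with normalized-histogram
    comparison metrics (correlation, Chi-square, intersection,
    Bhattacharyya), grey-level co-occurrence matrix (GLCM) Haralick texture
    statistics with per-feature Welch t-tests and principal-component
    comparison, expert visual-scoring arithmetic, and a mode-collapse
    diversity score. Includes a seeded phantom-image simulator of
    embryo-like culture-well frames with ground-truth masks, lossless
    4-fold rotation augmentation, block-mean resizing, an Adam optimizer
    implemented from its moment-update equations, and a command-line
    interface binding the full pipeline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
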