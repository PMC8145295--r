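Package: lesionkit
Title: Dermoscopy Lesion Enhancement, Deep Saliency Segmentation and
    Optimized-Feature Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale toolkit for multiclass skin lesion analysis:
    hybrid local contrast stretching of dermoscopy images, saliency-map
    lesion segmentation driven by a small trainable convolutional network
    with superpixel and morphological refinement, wrapper feature selection
    by an improved moth-flame optimizer with a cubic-SVM fitness,
    correlation-based fusion of two feature streams, and a kernel extreme
    learning machine classifier. Ships a synthetic dermoscopy-like fixture
    generator so every stage runs and is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    e1071,
    jsonlite,
    png,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
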