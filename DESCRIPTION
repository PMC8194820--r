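Package: chilimoments
Title: Symptom-Based Chili Leaf Disease Identification from Image Moments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An image-analysis pipeline for identifying foliar diseases of
    chili (Capsicum annuum) from leaf photographs: preprocessing (resize,
    Gaussian denoising, RGB to HSV conversion), fuzzy c-means pixel
    clustering to isolate the symptom-bearing region of interest, geometric
    image moments of lesion pixels as shape features, and nearest-match
    classification by Pearson's coefficient of correlation against a trained
    feature-vector dataset. Includes a seeded synthetic leaf-image generator
    covering five symptom classes (bacterial leaf spot, powdery mildew, leaf
    curl, Fusarium wilt, healthy), confusion-matrix evaluation metrics, and
    an end-to-end reproducible pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    tibble,
    withr,
    yaml
Suggests:
    e1071,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
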