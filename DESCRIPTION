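Package: dyegg
Title: Double-Yolk Duck Egg Identification from Candling Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies double-yolked (DY) versus single-yolked (SY) duck
    eggs from transmittance (candling) images. Provides a deterministic
    preprocessing chain (channel separation, median filtering, Otsu
    segmentation, padded square cropping, background masking, bicubic
    resizing to a 32x32 region of interest), yolk-shape description via
    normalized Fourier descriptors of the traced yolk boundary, and two
    classifiers built from first principles: Fisher's linear discriminant
    on the 14-dimensional descriptor vector with leave-one-out
    cross-validation, and a small LeNet-style convolutional network trained
    by minibatch stochastic gradient descent. A synthetic candled-egg image
    generator with ground-truth yolk masks makes the full pipeline testable
    without access to real egg images.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    purrr,
    tidyr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    png,
    readr,
    withr
Suggests:
    testthat (>= 3.0.0),
    optparse,
    MASS,
    tiff
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
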