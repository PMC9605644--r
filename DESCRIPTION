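Package: gemaseg
Title: Real-Time Brightfield Cell Segmentation with Gabor Filters and
    Adaptive Threshold Scheduling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Segments adherent cell cultures in time-lapse brightfield
    microscopy of microfluidic devices and tracks the percent image area
    covered by cells toward confluence or through drug-induced apoptosis.
    The core engine filters each frame with a four-orientation Gabor bank,
    binarizes the texture response with a locally adaptive threshold whose
    integer offset parameter is scheduled online from a linear regression
    over the per-frame coefficient of variation, and cleans the mask with
    morphological closing and dilation. A morphological-gradient baseline
    segmenter, a VIA polygon gold-standard reader with accuracy/Dice
    evaluation, a seeded synthetic time-lapse generator, and offline/online
    batch drivers are included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
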