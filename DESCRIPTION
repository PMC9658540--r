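Package: ltdetect
Title: Class-Aware Loss Reweighting for Long-Tailed Object Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying class-imbalance loss reweighting in single-shot
    object detection. Implements per-species loss weights built from instance
    censuses (a class-aware multiplying term and a class-balanced term), the
    multibox loss family (SmoothL1 localization, cross-entropy and focal
    classification, hard negative mining), default-box generation, IoU
    matching and offset encoding, greedy non-maximum suppression, and
    average-precision evaluation at IoU 0.5. A seeded synthetic scene
    generator produces long-tailed multi-object datasets (Zipf species
    frequencies, low foreground-background contrast, Pascal VOC XML
    annotations) on which a deliberately tiny CPU-trainable single-shot
    detector exercises the loss schemes end to end. All user-facing results
    are tibbles, with broom-style tidy()/glance() and ggplot2 autoplot()
    methods.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    xml2,
    png,
    jsonlite,
    yaml,
    grDevices,
    stats
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
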