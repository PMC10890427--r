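Package: microfract
Title: Microfracture Detection, Morphometrics and Weibull Statistics for CT Slice Stacks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and isolates fatigue microfractures in grayscale computed-tomography
    slice stacks of small material specimens (cortical bone and other industrial
    materials). Provides the full analysis chain: binarization and morphological
    clean-up, edge-based and morphological region extraction, per-feature
    morphometrics (area, perimeter, characteristic length, circularity,
    orientation, eccentricity) in pixels and microns, two-parameter Weibull
    characteristic-length statistics over detected fracture lengths by
    probability-plot rank regression, 3D connected-component reconstruction with
    volumetric density, a compact convolutional image classifier trained with
    stochastic gradient descent with momentum, and a synthetic stack generator
    with planted ground truth that makes every stage testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    igraph,
    png,
    tiff,
    jsonlite,
    tibble,
    dplyr,
    purrr,
    readr,
    ggplot2,
    generics,
    rlang,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    fitdistrplus,
    optparse,
    withr
Config/testthat/edition: 3
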