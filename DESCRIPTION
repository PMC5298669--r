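Package: flytrax
Title: Multi-Fly Video Tracking with Heading-Direction Identity Confirmation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects and tracks multiple walking fruit flies (Drosophila
    melanogaster) in grayscale arena videos. Foreground is isolated with a
    per-pixel mode background model, intensity-drift correction and
    Laplacian-of-Gaussian blob filtering; posture (best-fit ellipse and a
    signed heading direction disambiguated by wing-pixel scoring) is measured
    per blob; identities are maintained with a constant-velocity Kalman
    filter, Hungarian assignment on predicted positions, a heading-direction
    confirmation gate, and closest-neighbor reassignment of rejected pairs.
    Includes a synthetic arena-video generator with ground truth so the whole
    pipeline is testable end to end, plus tidy accessors and ggplot2
    visualisations of trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
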