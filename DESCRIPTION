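Package: prawnvision
Title: Predator-Vision Camouflage Analysis for Colour-Changing Prawns
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies camouflage of green and red chameleon prawns against
    seaweed backgrounds through the eyes of predatory fish. Converts
    calibrated multispectral images (standard-based linearisation and
    equalisation) into cone quantum catches for a dichromatic pollack and a
    trichromatic two-spotted goby visual model, computes receptor-noise
    limited chromatic discrimination (just noticeable differences), hue
    ratios and colour-change trajectories, and analyses behavioural
    substrate-choice trials with an exact binomial test. Ships a synthetic
    data generator (reflectance spectra, rendered camera fixtures,
    colour-change schedules, choice trials) with known ground truth so the
    whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    pracma,
    yaml,
    tibble,
    dplyr,
    tidyr,
    rlang,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    tiff,
    lme4,
    lmerTest,
    emmeans,
    ggplot2,
    readr
Config/testthat/edition: 3
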