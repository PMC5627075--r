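Package: battenberg
Title: Global Image Contrast Models and Battenberg Contrast-Matching Simulations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how global image contrast is computed.
    Generates 'Battenberg' stimuli (checkerboard arrangements of grating
    micro-patterns whose two interdigitated components carry independent
    Michelson contrasts), computes classical global-contrast metrics
    (Michelson, max, sum, average, energy, RMS) and transducer-based models
    (a summed Legge-Foley transducer and a wide-field contrast gain-control
    model with separate excitatory and suppressive pooling), optionally
    behind a log-Gabor spatial-filtering front end.  Predicts
    contrast-matching functions (points of subjective equality) for each
    model with no free parameters, simulates two-interval forced-choice
    matching experiments with 1-up-1-down staircases and cumulative
    log-Gaussian psychometric fits, and compares models by RMS error in dB.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    png,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
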