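Package: echoclick
Title: Detection, Clustering and Classification of Odontocete Echolocation Clicks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A desk-scale pipeline for discovering and classifying toothed-whale
    echolocation click types in long-term passive acoustic recordings: an
    energy-based impulse detector with band, amplitude, duration and merge
    rules; per-cluster 5-minute-bin features (mean normalized spectra,
    inter-click-interval distributions, waveform envelopes); two-phase
    unsupervised clustering with the Chinese Whispers label-propagation
    algorithm and normalized-mutual-information partition selection; a
    feed-forward neural-network bin classifier with data augmentation; and
    confusion-matrix evaluation with relative acoustic presence. A synthetic
    scene generator reproduces the statistical structure of ten Hawaiian
    click types so every stage can be exercised without hydrophone data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    graphics,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    igraph,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
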