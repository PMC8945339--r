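Package: myokinet
Title: Contraction Kinematics and Calcium-Transient Metrology for Isolated Cardiomyocytes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the contractile cycle and calcium handling of isolated
    adult cardiomyocytes from microscopy video. Tracks the two tails of a
    paced rod-shaped cell by normalized cross-correlation template matching
    with sub-pixel refinement, derives per-beat maximum displacements,
    fraction shortening, and peak-based force/contractility/energy
    parameters. Extracts background-subtracted f/f0 fluorescence traces from
    a signal region of interest, detrends them, and performs bi-level
    waveform transition metrology in the style of IEEE Std 181 (histogram
    state levels, 10/50/90% reference-level crossings, per-beat tau
    statistics, robust outlier discard, transient amplitude). A seeded
    synthetic generator produces ground-truthed videos and transient trains
    so the whole pipeline is testable without microscope data. Includes
    Welch's t-test and regression/Spearman reporting for two-group
    comparisons and a batch driver for many cells.
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
    graphics,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
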