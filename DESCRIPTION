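Package: whiskerpad
Title: Tactile Gradient Analysis Across the Rodent Whisker Pad
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Analysis pipeline for texture and edge coding experiments on the
    rodent mystacial pad: synthetic whisker-vibration and trigeminal spike
    train generation with known ground truth, excursion-threshold epoching of
    edge collisions versus texture stimulation, per-trial vibration and
    firing-rate features (position SD, 5-250 Hz band power, curvature SD,
    windowed firing rates), ideal-observer ROC/AUC texture discrimination
    with a trial-shuffle permutation null, multi-whisker pooling with a
    supralinearity index, and rostro-caudal gradient statistics (grain-size
    regressions, slope normalization, one-way ANOVA with Tukey contrasts).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    ggplot2,
    jsonlite,
    rlang,
    signal,
    stats,
    utils,
    grDevices,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
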