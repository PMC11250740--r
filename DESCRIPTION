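Package: ephysflow
Title: Spike, Spectral and Directed-Connectivity Analysis for Paired Cortical Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for extracellular electrophysiology from
    two simultaneously recorded cortical regions. Classifies sorted spike units by
    trough-to-peak waveform width and firing rate, labels stimulus-evoked responses
    from peri-stimulus time histograms with a bounded modulation index, estimates
    multitaper relative power spectral density in canonical frequency bands with
    point-by-point FDR-corrected group comparison, and quantifies directed
    functional connectivity between regions by generalized partial directed
    coherence (gPDC) from multivariate autoregressive model fits. Includes a
    synthetic-session generator (inhomogeneous Poisson spike trains, two-width
    spike waveforms, stable vector-autoregressive local field potentials with
    controllable directional coupling) so every stage has a parameter-recovery
    test with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
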