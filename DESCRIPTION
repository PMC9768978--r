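Package: meaburst
Title: Network Burst, Wavelet, and Propagation Analysis for
    Microelectrode Array Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for in vitro neural activity recorded on
    microelectrode arrays (MEA): amplitude-threshold spike detection on
    high-pass filtered extracellular traces, four-step network-burst
    detection with a ten-parameter burst panel, complex-Morlet continuous
    wavelet transform scalograms with per-pixel band quantification of
    low-frequency components, propagation- and axonal-conduction-velocity
    estimation from spike latencies on standard and high-density (CMOS)
    arrays, and dose-response statistics (one-way ANOVA with Dunnett's
    many-to-one comparisons, principal component analysis, pairwise
    MANOVA, paired t-tests). Includes a seeded synthetic-recording
    generator with full ground truth for validating every stage.
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
    jsonlite,
    multcomp,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
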