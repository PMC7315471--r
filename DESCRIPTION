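Package: eegmicrostates
Title: Resting-State EEG Microstate Analysis with Source Localization and
    Group Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: End-to-end pipeline for resting-state EEG microstate analysis:
    signal conditioning (zero-phase band-pass, anti-aliased downsampling,
    epoching, average reference), two-level polarity-invariant modified
    k-means clustering of global-field-power peak topographies, canonical
    class ordering, backfitting, and the standard microstate parameters
    (mean duration, time coverage, global explained variance, occurrence).
    Includes standardized minimum-norm (sLORETA-style) source localization
    of microstate templates with permutation max-statistic correction of
    voxelwise group contrasts, group-level statistics (pooled two-sample
    t-tests from raw data or printed summaries, mixed repeated-measures
    ANOVA, Bonferroni correction, generalized linear models, chi-square
    tests, post-hoc power), and a ground-truthed synthetic EEG generator
    so that every stage can be validated against known latent structure.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    signal,
    jsonlite,
    withr,
    MASS,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
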