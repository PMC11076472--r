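Package: taufisher
Title: Circadian Time Prediction from a Single Transcriptomic Sample
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts circadian time from a single bulk or pseudobulk
    transcriptomic sample. Training combines JTK_Cycle-style and
    Lomb-Scargle rhythmicity detection to select a predictor gene set,
    penalized Fourier-basis functional data analysis to smooth each
    gene's log-expression time course, within-sample pairwise
    gene-difference normalization, principal component analysis, and a
    multinomial regression over hourly classes on the 24-hour circle.
    Also provides circular statistics (wrapped prediction error,
    circular mean/SD, Rao homogeneity and Wallraff angular-distance
    tests), pseudobulk construction from sparse single-cell counts, a
    bootstrap procedure for quantifying circadian phase heterogeneity
    across cell types, and single-cell circadian expression simulators.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    methods,
    jsonlite,
    minpack.lm,
    nnet,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
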