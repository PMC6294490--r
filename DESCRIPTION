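Package: RepliFoci
Title: Single-Cell Replication Timing from Two-Color Operator-Array Foci
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for measuring locus-specific DNA replication timing in
    single cells from two-color time-lapse fluorescence imaging of lacO/tetO
    operator arrays. Includes 3D difference-of-Gaussians spot detection,
    nearest-neighbour tracking with gap closing, background-subtracted focus
    intensity quantification, bleach-aware sigmoid fitting of focus intensity
    traces, per-cell replication-time delays and rates, cohort statistics with
    Monte Carlo (permutation) resampling significance tests, companion in
    vitro analyses (two-state van 't Hoff fits of G-quadruplex UV-melting
    curves and primer-extension gel densitometry), and a fully parameterized
    synthetic-data generator that renders ground-truthed intensity traces and
    3D movies for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    graphics,
    grDevices,
    utils,
    Rcpp,
    minpack.lm,
    pracma,
    zoo,
    tiff,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
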