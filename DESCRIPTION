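Package: cyanorhythm
Title: Circadian Rhythm Analysis of Cyanobacterial Culture Backscatter
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies circadian oscillations in plate-reader backscatter time
    series from cyanobacterial cultures. Removes the culture growth trend with a
    polynomial fit, normalizes and smooths the oscillatory signal, fits a bounded
    simple-harmonic (cosinor-style) model to estimate free-running period, phase
    and amplitude, and derives dampened-oscillation metrics (first-cycle period,
    first-peak phase shift and relative amplitude versus a reference strain) via
    prominence-based peak detection. Includes the pairwise strain-comparison
    statistics cascade (Levene's test followed by Student's or Welch's t-test), a
    phylogenetic-profiling co-occurrence analysis (right-sided Fisher's exact
    tests with Benjamini-Hochberg correction), stoichiometric mass bookkeeping
    for clock-protein complexes, and a synthetic plate-data generator for
    validating the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
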