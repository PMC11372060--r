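#!/usr/bin/env Rscript
# Full rhythm analysis of the simulated panel: detrend, normalize, smooth,
# bounded cosine fits, first-peak phase/amplitude versus the wild type,
# first-cycle periods, and the pairwise statistics cascade. Outputs land in
# results/rhythm/.

suppressPackageStartupMessages(library(cyanorhythm))

if (!file.exists("results/plate_long.csv")) {
  stop("run analysis/01_simulate_plate.R first")
}

# height thresholds are in normalized backscatter units and therefore scale
# with the generator amplitude (A0 = 80): 10 sits well below both strains'
# smoothed amplitudes and ~8 sd above smoothed noise. Edge trimming excludes
# the zero-padding artifact of the smoothing kernel from peak search.
cfg <- run_config(
  reference_strain = "WT",
  detrend = detrend_config(edge_trim = TRUE),
  period_peaks = peak_params(min_distance = 150, min_height = 10)
)

res <- run_backscatter_analysis("results/plate_long.csv", cfg,
                                out_dir = "results/rhythm")
print(res)

cat("\nFirst-peak comparisons against the wild type:\n")
print(res$comparisons, row.names = FALSE)
cat("\nFirst-cycle periods per strain:\n")
print(res$first_periods, row.names = FALSE)
cat("\nPairwise strain tests on first-cycle periods:\n")
print(res$period_tests, row.names = FALSE)
cat("\nThe wild-type cosine fit reads low (~25.1 h for a 26 h generator):\n",
    "a quartic detrend absorbs part of a 3.2-cycle oscillation and biases\n",
    "the fitted period; see the methods vignette for the analysis.\n")
cat("\nwrote results/rhythm/\n")
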