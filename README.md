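# cyanorhythm

Quantifies circadian oscillations in plate-reader **backscatter time series**
from cyanobacterial cultures, and the comparative statistics around them. It
is aimed at chronobiologists who record growth/backscatter in microbioreactor
plates (e.g. 4–5 replicate wells per strain, sampled every 5 min for 84 h
under constant light) and want per-strain period, phase and amplitude
estimates plus defensible mutant-versus-wild-type comparisons.

The core model is a bounded cosinor fit to the growth-detrended signal,

```
y(t) = A cos(ω t + φ),      0 ≤ A ≤ max(y) − mean(y),
                            2π/45 ≤ ω ≤ 2π/18  (rad/h),
                            2π/12 ≤ φ ≤ 2π,
```

with the free-running period `P = 2π/ω`. Strains whose oscillation is
dampened (and therefore poorly described by a single cosine) are instead
summarized by prominence-based peak features of the first cycle: the
first-cycle period `2·|t(first peak) − t(first trough)|`, and the first-peak
**phase shift** and **relative amplitude** against a reference strain with
the error boundaries `SD_mut + SD_ref` and `SD_mut/h_mut + SD_ref/h_ref`.
Strain pairs are tested with a Levene → Student/Welch cascade. Two further
components round out the analysis: a phylogenetic-profiling co-occurrence
network (right-sided Fisher's exact tests within an anchor-restricted genome
universe, Benjamini–Hochberg at FDR 0.01) and stoichiometric mass
bookkeeping for clock-protein complexes.

A synthetic-data generator (growth trend + start-up transient + optionally
damped cosine + Gaussian noise, with deterministic per-well seeds) stands in
for the deposited raw data, so the whole pipeline is testable end to end.
See the methods vignette (`vignettes/backscatter-rhythms.Rmd`) for the
models, parameter choices, and the characterized biases of polynomial
detrending.

## Worked example

The `analysis/` scripts run the full workflow on a simulated three-strain
panel (wild-type-like 26 h rhythm; a near-arrhythmic low-amplitude 33 h
strain; a damped strain peaking 7 h early at 1/3 amplitude):

```sh
Rscript analysis/01_simulate_plate.R 1     # -> results/plate_long.csv
Rscript analysis/02_rhythm_analysis.R      # -> results/rhythm/
Rscript analysis/03_cooccurrence.R 1       # -> results/cooccurrence/
Rscript analysis/04_stoichiometry.R        # -> results/stoichiometry_*.csv
```

`02_rhythm_analysis.R` prints, for seed 1:

```
     strain n_wells amplitude period_h phase_rad        rss r_squared converged
         WT       5 70.694994 25.11405 0.5235988 491471.856 0.8317261      TRUE
 dKaiA1B1C1       5  6.997496 29.69183 6.2831853   3831.184 0.8629136      TRUE
 dKaiA3B3C3       5 12.699071 25.57341 2.5730171  40979.454 0.6731536      TRUE

First-peak comparisons against the wild type:
     strain reference phase_shift_h phase_shift_err_h relative_amplitude
 dKaiA1B1C1        WT          6.15          2.010245          0.1393810
 dKaiA3B3C3        WT         -7.15          1.179738          0.3391899
```

Reading this: the wild type is well fitted by a single cosine (R² 0.83)
with a ~25.1 h period — the generator's rhythm is 26 h, and the ~0.9 h
shortfall is the characterized bias of quartic detrending over 3.2 cycles
(see the vignette), which affects all strains alike. The damped mutant's
first peak comes 7.15 ± 1.18 h earlier than the wild type's at 0.34× its
amplitude, recovering the generator's −7 h / one-third settings. The
co-occurrence driver recovers the planted kaiA3–kaiB3–kaiC3 module as a
3-clique (all three pairwise BH-adjusted p ≈ 10⁻¹⁰), and the stoichiometry
driver prints the 348 kDa KaiC3 hexamer, the 840 kDa
KaiC3₆·(KaiA3₂)₆·(KaiB3)₆ assembly, and the 1:0.8 titration ratio of
4.2 µM KaiA3 against 3.4 µM KaiC3.

Programmatic use mirrors the scripts:

```r
library(cyanorhythm)
plate <- read_plate_long("results/plate_long.csv")
cfg <- run_config("WT", detrend = detrend_config(edge_trim = TRUE),
                  period_peaks = peak_params(min_distance = 150, min_height = 10))
res <- run_backscatter_analysis(plate, cfg, out_dir = "results/rhythm")
res$fits$strains
res$comparisons
```

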