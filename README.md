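# RepliFoci

Single-cell DNA replication timing from two-color time-lapse imaging of
lacO/tetO operator arrays, for researchers studying replication-fork
progression through difficult templates (e.g. G-quadruplex structures) in
budding yeast.

## The measurement

Two operator arrays flank a ~20 kb chromosomal interval next to an
early-firing origin; lacI-GFP and tetR-tdTomato make them visible as a green
and a red focus. When the fork duplicates an array, twice the repressor can
bind and the focus intensity doubles. Each channel is fitted with a bleached
logistic step

    I(t) = exp(-k_b t) * (B + A / (1 + exp(-(t - t_mid)/tau)))

and the per-cell replication delay is Δt = t_mid(red) − t_mid(green), the
time to replicate the mid-array-to-mid-array interval (30 kb in the nominal
construction: 20 kb spacing plus two half arrays of 10 kb). 30/Δt is a
single-cell replication rate in kb/min. Cohorts are summarized as mean ± SEM
and compared with a Monte Carlo resampling (label permutation) test on the
difference of means, p = (k+1)/(B+1) with 10^6 iterations by default.

The package covers the full chain — 3D difference-of-Gaussians spot
detection, nearest-neighbour tracking with gap closing, background-
subtracted 3D intensity quantification, sigmoid fitting with QC, cohort
statistics — plus the in vitro companions (two-state van 't Hoff fits of G4
UV-melting curves; primer-extension gel densitometry) and a ground-truthed
synthetic-data generator (traces, full 5D movies, melting curves, gel
lanes) used to validate every stage.

## Worked example

Simulate a wild-type-like cohort and a cohort slowed 2-fold by a folded
obstacle, run the pipeline on traces, and compare:

```r
library(RepliFoci)
layout <- nominalLocusLayout()
locusGeometry(layout)$mid_to_mid_kb
#> [1] 30

e_dt0 <- 30 / 1.5 * (1 + 0.25^2)   # expected null delay, min
wt  <- simulateCohortTraces(layout, scenarioConfig("wt", n_cells = 45, seed = 21))
g4  <- simulateCohortTraces(layout, scenarioConfig("g4", n_cells = 25, seed = 22,
         folded_fraction = 1, pause_mean = e_dt0))

ev_wt <- qcFilter(fitCohortTraces(wt$traces)$events)$passed
ev_g4 <- qcFilter(fitCohortTraces(g4$traces)$events)$passed
rep_ <- compareCohorts(list(wt = ev_wt, g4 = ev_g4),
                       n_iterations = 1e5, seed = 23)
rep_$comparisons[, c("label", "n", "mean_delta_t", "sem", "p_value",
                     "stars", "delta_t_ratio")]
#>   label  n mean_delta_t      sem    p_value stars delta_t_ratio
#> 1    g4 25     38.56417 3.037061 9.9999e-06  ****       1.86053
```

The g4 cohort's mean delay is ~1.9× the wild-type's (configured: 2.0,
within this cohort size's sampling spread), the
permutation test calls the difference highly significant, and the delay
ratio equals the fold-decrease in replication rate. Full 3D movies run
through the same chain with `simulateReplicationMovie()` →
`movieToEvents()`.

Melting curves and gels:

```r
fitTwoStateMelting(simulateMeltingCurve(Tm = 55, dH = 45, noise_sd = 0.01,
                                        seed = 4))
#> MeltingFit: Tm = 55.15 degC, dH = 44.5 kcal/mol, r2 = 0.9996
quantifyGelTimecourse(simulateGelTimecourse(0.25, times = c(1, 2, 4, 8),
                                            seed = 5))
#>   time full_length_fraction
#> 1    1            0.2559105
#> 2    2            0.4126975
#> 3    4            0.6220150
#> 4    8            0.8342631
```

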