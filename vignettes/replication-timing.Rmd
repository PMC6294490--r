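---
title: "Measuring single-cell replication timing from two-color operator-array foci"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring single-cell replication timing from two-color operator-array foci}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
set.seed(1)
library(RepliFoci)
```

## The measurement

A yeast chromosome is engineered so that two operator arrays flank the
interval of interest near an early-firing origin: a lacO array (bound by
lacI-GFP, the *green* focus) proximal to the origin, and a tetO array (bound
by tetR-tdTomato, the *red* focus) distal to it. When the replication fork
duplicates an array, twice as many repressor-fluorophore fusions can bind,
so the focus intensity doubles. In a time-lapse movie each focus therefore
traces a step: baseline $B$, then a rise of amplitude $A \approx B$ around
the time the array is replicated. We model a channel's intensity as a
bleached logistic step,

$$I(t) = e^{-k_b t}\left(B + \frac{A}{1 + e^{-(t - t_{1/2})/\tau}}\right),$$

where $t_{1/2}$ is the *mid-rise point*, $\tau$ the rise scale and $k_b$ a
mono-exponential photobleaching rate. The per-cell replication delay is

$$\Delta t = t_{1/2}^{\mathrm{red}} - t_{1/2}^{\mathrm{green}},$$

the time the fork needs to travel from the middle of the green array to the
middle of the red array. With the nominal construction — 10 kb arrays whose
inner edges are 20 kb apart — that interval is 30 kb (each array contributes
half its length), so $30/\Delta t$ is a single-cell replication rate in
kb/min. The coordinate-accurate layout on chromosome IV (insertions at
332,960 and 352,560 bp with 11 kb arrays; a G-quadruplex motif at 344,119 bp,
8.4 kb before the distal array) gives 30.6 kb and is available as
`chrIVLocusLayout()`; reported rates state which distance was used.

```{r geometry}
locusGeometry(nominalLocusLayout())
locusGeometry(chrIVLocusLayout())
```

## What the synthetic data emulate

No raw movies ship with the package; a generator reproduces the statistical
structure the analysis relies on, with known ground truth, so every stage is
testable end to end.

* **Kinetics** (`sampleCellKinetics()`): each cell draws a fork speed from a
  log-normal law — mean 1.5 kb/min and cell-to-cell CV 0.25 by default, which
  puts the wild-type delay near 20 min over 30 kb with a realistic spread.
  The log-normal was chosen for positivity and right skew, the standard
  choice for rates; the paperless alternatives (gamma, truncated normal)
  would serve equally and are not exposed. Origin firing adds a normal
  offset (30 ± 5 min after acquisition start, placing both steps comfortably
  inside a 3-h movie).
* **Obstacle pauses**: a thermally stable obstacle such as a G-quadruplex is
  modelled as all-or-none per cell: with probability `folded_fraction` the
  cell carries a folded structure and adds a pause drawn from an exponential
  law with mean `pause_mean` (memoryless escape from a single barrier); a
  fixed-pause mode exists for deterministic tests. Cells with an unfolded
  obstacle replicate at wild-type speed — this bimodality is exactly what a
  two-state obstacle predicts for single-cell data.
* **Traces and movies** (`renderTrace()`, `renderMovie()`): the logistic
  step with $A = B$ (doubling), rise time defaulting to the time a fork
  needs to duplicate a 10 kb array (~6.7 min), multiplicative
  mono-exponential bleaching per channel (the simplest model consistent with
  constant illumination), and — in movies — 3D Gaussian foci (PSF sigmas
  0.13/0.6 um) on a uniform background with Poisson shot noise, Gaussian
  read noise and a per-cell random-walk drift. Acquisition defaults follow
  the assay: 1-min frames, 12 z-sections 0.7 um apart.

What the generator does **not** emulate: cell bodies and nuclei (only the
two foci are rendered — whole-cell segmentation is out of scope), cell
division and lineage, focus photophysics beyond shot/read noise and
mono-exponential bleaching, and movement beyond diffusive drift. Passing
tests therefore validate the measurement chain given foci that behave like
tagged loci; they cannot certify robustness to segmentation errors or
crowded fields.

```{r traces, fig.height = 4}
layout <- nominalLocusLayout()
sim <- simulateCohortTraces(layout, scenarioConfig(n_cells = 4, seed = 7))
fits <- fitCohortTraces(sim$traces)
plotTrace(sim$traces[[1]], fits$fits[[1]])
```

## From movies to events

Detection is a difference-of-Gaussians band-pass at the spot scale (small
sigma = the PSF, large = twice that, per-axis in voxels so the 0.7-um
z-step is handled explicitly), 26-neighbour local maxima above `k_sigma = 5`
robust noise units (MAD of the band-passed volume), and an
intensity-weighted sub-voxel centroid. Maxima inside a small boundary
margin are discarded: the filter's mirror padding inflates variance there,
and an edge spot could not be quantified anyway. Co-detections closer than
0.5 um merge with summed response — a duplicating locus can transiently
resolve into sister foci, and the assay reads their total fluorescence.

Intensity is always integrated on the *raw* volume (band-passing distorts
integrated intensities) over a PSF-shaped ellipsoid (z semi-axis stretched
3-fold), minus the median of a surrounding shell times the core size; a
shell clipped by the volume edge flags the measurement. Tracking is greedy
nearest-neighbour linking in physical units with gap closing (ties broken
by distance, then intensity; on well-separated foci it coincides with
exhaustive minimal-cost matching, which the tests verify). Green and red
tracks pair by mutual nearest median position; unpaired tracks are reported
and excluded, and gaps stay `NA` — never interpolated.

Fitting estimates all five step parameters per channel by bounded
Levenberg-Marquardt. Bleaching is estimated *inside* the fit rather than
removed by pre-detrending, which would bias a step; initialization uses the
first/last quartile medians ($B$, $A$), the maximum of the smoothed first
difference ($t_{1/2}$), three frame intervals ($\tau$), and a near-zero
bleach rate, with a short ladder of fallback starts (amplitude prior
$A = B$) because a step close to the window edge can leave the data-driven
amplitude estimate near zero. Non-convergence is reported, never thrown.

QC (all reasons machine-readable): both channels converged, $r^2 \ge 0.8$,
plateau fold-increase $(B+A)/B$ within $[1.4, 2.6]$ (a clean duplication
doubles), both mid-points at least 5 min inside the observation window, and
$\Delta t > 0$ by default — a negative delay means the locus was replicated
by a fork arriving from the distal side, which the assay's orientation
assumption excludes; such cells are flagged `reverse_orientation` and can
be retained with `require_positive_delta = FALSE`.

## Cohort statistics

`summarizeCohort()` reports $n$, mean $\Delta t$, SEM (sample sd over
$\sqrt{n}$) and a histogram anchored at zero. Significance between two
cohorts uses a Monte Carlo resampling test: per-cell delays are pooled,
labels reshuffled preserving group sizes, and the absolute difference of
means recomputed; $p = (k + 1)/(B + 1)$ with $k$ exceedances in $B$
iterations — never exactly zero. The default is $B = 10^6$; the test suite
uses $10^4$. The difference of means is the statistic because the reported
cohort quantities are means with SEM error bars; a pooled-bootstrap variant
(`method = "bootstrap"`) is provided for sensitivity analysis, and no
multiple-testing correction is applied (per-comparison stars at 0.05,
0.005, 0.0005, 0.00005). Fold-changes are delay ratios, which equal
rate fold-decreases over a common distance.

```{r cohorts}
e_dt0 <- 30 / 1.5 * (1 + 0.25^2)  # expected null delay, min
wt <- sampleCellKinetics(layout, scenarioConfig("wt", n_cells = 45, seed = 21))
g4 <- sampleCellKinetics(layout, scenarioConfig("g4_pif1d", n_cells = 25,
  seed = 22, folded_fraction = 1, pause_mean = e_dt0))
rep_ <- compareCohorts(list(wt = wt$delta_t_true, g4_pif1d = g4$delta_t_true),
                       n_iterations = 1e4, seed = 23)
rep_$comparisons
```

## In vitro companions

**Melting curves.** G-quadruplex stability is read from UV melting at
295 nm. `normalizeMelting()` fits linear baselines to the lowest- and
highest-temperature quartiles and rescales the signal to an apparent folded
fraction (normalization is exactly invariant to affine transforms of the
raw signal). `fitTwoStateMelting()` fits the unimolecular two-state van 't
Hoff model

$$\theta(T) = \frac{1}{1 + \exp\!\big(-\tfrac{\Delta H}{R}(\tfrac1T - \tfrac1{T_m})\big)}$$

in absolute temperature, with $\Delta S = \Delta H / T_m$ fixed by the
midpoint condition — the standard all-or-none form, adopted here as the
reference model. $\theta(T_m) = 0.5$ by construction. A transition not
bracketed by the data is diagnosed rather than extrapolated, and an
increasing (refolding-type) curve fits with $\Delta H < 0$ and is flagged.

**Gel densitometry.** Primer-extension products are quantified from 1D lane
profiles (image-to-profile extraction is out of scope). The baseline is a
smoothed morphological opening (rolling minimum then maximum, window wider
than a band), so narrow bands are flattened while negative corrected
intensities remain possible and are counted, never clipped. Band areas are
trapezoidal integrals over named windows; the *full-length fraction*
divides the full-length area by the summed extension-product areas. Whether
the unextended primer belongs in the denominator is a genuine reporting
ambiguity: the default excludes it (fraction of extended products), and
`include_primer = TRUE` reports the alternative, so both conventions are
one call apart.

```{r biochem}
fitTwoStateMelting(simulateMeltingCurve(55, 45, noise_sd = 0.01, seed = 4))
lanes <- simulateGelTimecourse(0.25, times = c(1, 2, 4, 8), seed = 5)
quantifyGelTimecourse(lanes)
```

## Numerical choices and problem sizes

* Geometry distances print at 0.1 kb, truncated toward zero, with exact
  values kept internally.
* Voxel indices are 0-based in (z, y, x) with voxel centres at
  $(i + 0.5)\,\times$ voxel size; genomic coordinates are 1-based bp as
  printed in strain tables.
* The permutation inner loop, the separable 3D Gaussian filter and the
  local-maximum scan are compiled (Rcpp) and draw from R's RNG, so results
  are reproducible under `set.seed()`.
* Tie-breaks: tracking assignments by distance then intensity; histogram
  bins are right-open.
* Degenerate inputs: flat traces fit with $A \approx 0$ and fail QC on the
  fold window; all-equal cohorts give SEM 0 and $p = 1$; zero-length arrays
  reduce the interval to the inner spacing.
* The test suite validates cohort-level recovery on 25-cell cohorts at the
  full acquisition geometry (128 x 128 x 12 voxels, 180 frames) and
  statistical calibration on 1000 null cohort pairs at $10^4$ iterations;
  generator-level checks use $10^5$ cells. These sizes were chosen so the
  whole suite stays desk-scale while keeping Monte Carlo error well below
  every tolerance tested.

## Known limitations

* The tracker is greedy: with foci closer than the frame-to-frame motion,
  identities can swap; the assay's two foci per cell are well separated, so
  this does not arise at the intended density.
* Bleaching is mono-exponential and shared across a channel; triplet-state
  or intensity-dependent photophysics would bias $k_b$ but hardly
  $t_{1/2}$, which is what the delay uses.
* The two-state melting fit reports van 't Hoff (model-dependent)
  enthalpies; calorimetric agreement is not implied.
* Cohort comparisons assume independent cells; batch or movie effects are
  not modelled.
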