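# geciq

Quantification tools for genetically encoded calcium indicators (GECIs),
built around the characterization workflow of soma-targeted red sensors
(FRCaMPi / SomaFRCaMPi class). The package is for sensor engineers and
imaging labs who need to (a) fit the biophysics of an indicator from
titration data, (b) compute the standard fluorescence-transient metrics
(ΔF/F₀, SNR, kinetics, responsiveness), (c) quantify spatial expression and
neuropil contamination, and (d) test how soma-targeting changes
population-level correlation structure — all validated against synthetic
data with known ground truth.

## The models at the core

**Hill transduction.** Indicator fluorescence versus free calcium is

    F([Ca2+]) = F_apo + (F_sat − F_apo) · [Ca2+]^n / ([Ca2+]^n + Kd^n)

with dissociation constant `Kd` (nM), Hill coefficient `n`, and dynamic
range `F_sat/F_apo`. `fit_hill_titration()` recovers these by bounded
nonlinear least squares; `frcampi_params()` ships the published FRCaMPi
constants (Kd 81 nM, n 3.1, dynamic range 16.3, pKa 6.48).

**Transient metrics.** `ΔF/F₀ = (F − F₀)/F₀` with every common baseline
convention (pre-stimulus mean, sliding 10th/20th percentile windows, spline
fits) under one interface; peak SNR = ΔF_max / SD(baseline); half-rise and
half-decay from single-exponential fits with linear interpolation of the
half-maximum crossings (fits with R² < 0.8 flagged excluded); a
zero-crossing full-decay time; Wilcoxon and z-score (> 2.5 within 3 s)
responsiveness classifiers; orientation selectivity
`OSI = (R_pref − R_orth)/(R_pref + R_orth)`.

**Spatial quantification.** Expression along neurites decays as
`exp(−d/λ)`; soma-targeted sensors have λ ≈ 5× shorter, which is what
confines fluorescence to cell bodies. Neuropil is estimated from a 5–15 px
annulus (median, other ROIs excluded) and subtracted as
`F_corr = F − 0.7·F_neu`. ROIs are matched across channels by
highest-IOU-first pairing at IOU ≥ 0.5.

**Contamination experiment.** `run_contamination_experiment()` simulates one
field twice — identical geometry, activity and optics, differing only in
targeting — renders noisy movies, and compares raw versus 0.7-corrected
pairwise Pearson correlations by distance. Since simulated neurons fire
independently, any correlation is contamination by construction.

## Worked example

Fit a calcium titration measured on the standard 16-point free-calcium
series:

```r
library(geciq)
library(tibble)

grid  <- c(2.1, 7.9, 16.3, 35.4, 79.2, 135.5, 208.4, 312.6, 468.9, 731.5,
           1254.6, 2817.6, 5856.0, 11858.0, 21923.7, 81276)
curve <- tibble(x = grid, y = hill_fluorescence(grid, frcampi_params()))
fit   <- fit_hill_titration(curve)
fit
#> <geci_fit> model: hill_titration | R^2 = 1.0000 | converged: TRUE
#> # A tibble: 5 × 2
#>   term          estimate
#>   <chr>            <dbl>
#> 1 kd                81
#> 2 hill_n             3.1
#> 3 f_apo              1
#> 4 f_sat             16.3
#> 5 dynamic_range     16.3
```

`kd` is the calcium concentration of half-maximal response (81 nM — close
to neuronal resting calcium, which is what makes the sensor responsive to
single action potentials), `hill_n` the binding cooperativity, and
`dynamic_range` the saturated-to-apo brightness ratio (16.3-fold).
`tidy()`/`glance()` return these as tibbles; `autoplot(fit)` draws the
curve.

Run the soma-targeting contamination experiment at its default study
conditions (30 neurons, 128×128 µm, 600 frames at 10 Hz, wide-field
optics):

```r
ex <- run_contamination_experiment(contamination_config(), seed = 1)
ex
#> <geci_contamination>
#>   non_targeted  n=30 | near-pair PCC raw 0.425 -> corrected 0.120
#>   soma_targeted n=30 | near-pair PCC raw 0.210 -> corrected 0.049
```

Read: with a non-targeted sensor, nearby neurons (< 100 µm apart) show a
mean raw pairwise Pearson correlation of 0.425 although their activity is
independent — pure neuropil/out-of-focus contamination. Soma-targeting
halves it (0.210), and the standard 0.7 neuropil subtraction cuts the
non-targeted value about 3.5-fold (0.120). Uncorrected soma-targeted
recordings sit in the same low-correlation range as corrected non-targeted
ones — the package's in-silico analogue of the published ordering.
`ex$non_targeted$profile_raw` holds the distance-binned profile and
`plot_correlation_profile()` plots it.

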