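---
title: "Models and methods behind geciq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind geciq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

geciq quantifies the performance of genetically encoded calcium indicators
(GECIs) — in particular soma-targeted red sensors of the FRCaMPi family —
across the measurements that define such sensors: biophysical titrations,
fluorescence-transient statistics, spatial expression profiles, and
population-level correlation structure. Because the raw imaging data behind
such characterizations are rarely portable, the package pairs every analysis
stage with a synthetic-data generator that produces the same kind of data
with known ground truth, so each estimator can be validated end to end.

This vignette records the models, the tunable parameters and their defaults,
the numerical choices, and the design decisions taken where conventions were
genuinely open.

## Indicator biophysics

Fluorescence as a function of free calcium follows the Hill equation

$$F(\mathrm{[Ca^{2+}]}) = F_{apo} + (F_{sat}-F_{apo})
  \frac{\mathrm{[Ca^{2+}]}^n}{\mathrm{[Ca^{2+}]}^n + K_d^n},$$

with dissociation constant $K_d$ (nM), Hill coefficient $n$, and the
calcium-free/saturated brightnesses $F_{apo}, F_{sat}$. The dynamic range is
$F_{sat}/F_{apo}$ and is always derived from the brightness pair.
`frcampi_params()` carries the published FRCaMPi constants ($K_d$ = 81 nM,
$n$ = 3.1, dynamic range 16.3, saturated-state pKa 6.48), which seed all
simulations.

`fit_hill_titration()` uses bounded Levenberg–Marquardt least squares
(`minpack.lm::nlsLM`) with deterministic, data-driven initialization: $K_d$
starts at the half-range crossing of the curve (linear interpolation), $n$
at 2, brightness at the observed extremes. Bounds ($K_d \in (0, 10^6]$ nM,
$n \in (0, 10]$, brightness $> 0$) prevent sign-flip degeneracies. A curve
whose max/min ratio is below 1.05 is rejected as non-identifiable rather
than fitted. pH titrations use the same machinery with a sigmoid in pH
(Hill form in $[\mathrm{H^+}]$); photobleaching uses mono- or
bi-exponential decays, with the half-life reported as $\tau\ln 2$.

Calibration-buffer arithmetic: for reciprocal dilution of a chelator buffer
with its Ca-loaded counterpart at mixing fraction
$f = \mathrm{Ca_{total}}/\mathrm{chelator_{total}}$,

$$\mathrm{[Ca^{2+}]_{free}} = c \cdot K_d^{\mathrm{eff}} \cdot \frac{f}{1-f},$$

with the conventional correction factor $c = 1.084$. The effective chelator
$K_d^{\mathrm{eff}}$ depends on ionic strength, pH and temperature and has
no universal value, so it is a required argument; around 310–320 nM
reproduces commonly tabulated EGTA series approximately.

## Synthetic transients

Spike trains are homogeneous Poisson processes thinned by an absolute
refractory period, or deterministic field-stimulation schedules (trains of
1–160 pulses at 83 Hz, the standard culture protocol). Calcium follows a
linear exponential-kernel surrogate,

$$\mathrm{Ca}(t) = \mathrm{Ca}_{rest} +
  \sum_i A \, e^{-(t-t_i)/\tau_{Ca}}\,\mathbf{1}[t \ge t_i],$$

with defaults $\mathrm{Ca}_{rest}$ = 50 nM (neurons rest around 30–100 nM),
$A$ = 20 nM per action potential and $\tau_{Ca}$ = 1 s. With the FRCaMPi
Hill constants these values place the resting point on the steep flank of
the titration curve and produce single-AP responses of roughly
$\Delta F/F_0 \approx 0.8$, the right order for a sensitive red GECI. There
is no extrusion saturation or endogenous buffer pool: none of the
implemented metrics depend on those, and indicator buffering can be
emulated by scaling $A$ down. Fluorescence transduction is the pointwise Hill map
(equilibrium mode) or a single-site binding relaxation
$db/dt = k_{on}\mathrm{Ca}^n (1-b) - k_{off} b$ integrated with a
fixed-step explicit scheme (default 20 substeps per frame, with an
instability guard that tells the user to raise the substep count). Photon
noise is Poisson shot noise at a configurable photons-per-unit gain plus
Gaussian read noise.

Default frame rates mirror the imaging regimes the metrics come from:
20 Hz (culture), ~3–4 Hz (larval zebrafish confocal), 33 Hz and 7 Hz
(two-photon), ~1.1 Hz (volumetric brainstem stacks), 10 Hz (wide-field).

## Scenes, expression profiles and rendering

`build_scene()` samples non-overlapping somas (minimum center distance =
sum of radii, optionally plus a clearance) in a field of view, grows
random-walk neurite polylines from each soma, and rasterizes per-neuron
expression weight maps. Expression along a neurite decays as
$e^{-d/\lambda}$ with $d$ the arclength from the soma edge, so intensity
falls to $e^{-1}$ (36.8%) of the soma-edge value at one length constant.
Non-targeted sensors default to $\lambda$ = 100 µm; soma-targeted
(ribosome-tethered) sensors to $\lambda$ = 20 µm — a 5× shorter length
constant, the defining structural property of ribo-tagged indicators.
Pixel conventions are pinned for reproducibility: 0-based indices, (0,0)
top-left, positions in µm via the pixel size, masks as whole-pixel sets.

`render_movie()` composes each frame as in-focus soma fluorescence +
neurite (structural neuropil) fluorescence + an out-of-focus term + an
optional shared global neuropil trace + constant background, then applies
per-pixel noise. The out-of-focus term is a two-parameter caricature of
optical sectioning — a Gaussian blur of every neuron's footprint mixed in
with weight `oof_weight` — not a 3-D point-spread function; it is
sufficient to reproduce the wide-field ≫ two-photon contamination ordering,
which is what the analyses test. Because blur is linear and footprints are
static, each blurred footprint is computed once and scaled by its neuron's
trace, which keeps rendering fast. Neuropil is represented two ways, both
available: the structural route (every neuron's neurites, the default,
which produces distance-dependent artifactual correlation) and a shared
global trace mixed into non-soma pixels (plus its own out-of-focus bleed).

Presets: wide-field uses `oof_weight = 8`, blur σ = 60 px; two-photon uses
`oof_weight = 0.08`, σ = 2 px. The wide-field values encode a background
many times brighter than the in-focus somatic modulation, which is the
regime in which one-photon cortical imaging operates (raw pairwise
correlations there are dominated by scattered and out-of-focus light); they
were chosen so that the default contamination experiment operates in the
strong-contamination regime where the published ≥3-fold correction effect
is expressed, and they are deliberately not fitted to any quantitative
brightness measurement — the package reproduces orderings, not absolute
wide-field correlation magnitudes.

## Baselines and transient metrics

Every published $F_0$ convention used by the analyses is implemented under
one interface (`estimate_baseline()`): the pre-stimulus window mean (1 s,
culture), sliding low-percentile windows (20th percentile over 200 frames,
zebrafish; 10th percentile over a 60-s window, volumetric brainstem),
smoothing-spline fits to the whole trace (slow drift/photobleaching), and a
short polynomial spline through the 3 frames before a spike (wide-field
event analysis). Numerical choices that the conventions leave open are
pinned: sliding windows are centered and truncated (not padded) at the
edges; percentiles use the linear-interpolation definition
(`quantile type 7`); SDs are sample SDs ($n-1$) throughout.

Kinetics (`half_times()`) fit the rising segment with a saturating
exponential and the decaying segment with a decaying exponential, then
locate half-maximum crossings by linear interpolation between frames on the
fitted curves; half-rise is the time from the rising half-crossing to the
peak, half-decay from the peak to the falling half-crossing. Transients
whose fit $R^2$ falls below 0.8 are flagged excluded, mirroring the
standard fitting-coefficient exclusion rule. For a pure exponential the
half-decay is $\tau \ln 2$ to within one interpolation frame. Kinetic
recovery is validated on event-averaged waveforms (four repeats injected at
SNR 20, averaged with `event_triggered_average()`, sampled at 33 Hz): this
mirrors how kinetics are estimated in practice — from trial- or
spike-averaged traces — and a single unaveraged transient at SNR 20 sits at
the information limit where no estimator reaches 2% precision.

The full decay time is the time from the peak to the first post-peak
zero-crossing of $\Delta F/F_0$ (linear interpolation at the crossing); the
published phrasing ("the first time point that reached the negative of the
spike") is ambiguous, and the zero-crossing reading is flagged to the user.
Traces that never return are right-censored, not errors. The
whole-session low-quantile SNR denominator is similarly ambiguous and is
implemented as the SD of the frames at or below the 20th percentile
(`noise_basis = "low_quantile_sd"`).

Thresholded classifiers use strict inequalities where the source phrasing
says "exceeding" (z > 2.5 within 3 s of onset) and inclusive comparison
where it says "or greater" (IOU ≥ 0.5). The pre/post trial classifier
requires a Wilcoxon rank-sum p < 0.05 in at least one stimulus condition
(no multiple-testing correction, matching the published rule; Bonferroni is
available as an off-by-default flag) *and* a trial-averaged peak more than
4 baseline SDs above baseline. The rank-sum test is `stats::wilcox.test`,
which enumerates exactly for small untied samples and otherwise uses the
normal approximation with tie correction. The orientation selectivity
index is $(R_{pref}-R_{orth})/(R_{pref}+R_{orth})$; values above 1 (possible
with negative orthogonal responses) are reported but flagged, since such
neurons are conventionally excluded.

## Spatial quantification

ROI sets are integer label images. The neuropil annulus around an ROI is
the ring of background pixels whose Euclidean distance to the nearest ROI
pixel lies in (inner, outer] px (defaults 5 and 15), with pixels of *any*
ROI excluded; its per-frame median is the neuropil estimate, and
subtraction is $F - 0.7 F_{neu}$ with the standard 0.7 coefficient.
ROI matching across channels is greedy highest-IOU-first at threshold 0.5,
with ties broken deterministically by (lower id, lower id); whether the
published matching was greedy or globally optimal is unstated, so both are
exposed (`method = "optimal"` maximizes total IOU exhaustively) and the
test suite documents where they differ. Labeling density counts reference
ROIs covered by an indicator ROI (IOU ≥ 0.25 or centroid containment — an
artifact decision, since the published workflow used co-detection without a
stated rule), after removing edge-touching ROIs. `simple_segment()`
(Gaussian smooth → Otsu or absolute threshold → connected components →
area filter) is a deliberately minimal deterministic segmenter for bright
synthetic somata; it does not attempt to replace learned segmentation
tools, and the pipeline consumes ground-truth or user-supplied masks
everywhere segmentation quality matters.

## Population analysis and the contamination experiment

Pairwise Pearson correlations are computed between z-scored ROI traces for
all unordered pairs, with centroid-to-centroid distances in µm, and binned
into half-open distance bins [lo, hi) with default edges 0, 200, 400,
800 µm (a pair at exactly 200 µm falls in the 200–400 bin; pairs beyond the
last edge are dropped with their count reported).

`run_contamination_experiment()` is the package's end-to-end experiment:
one field simulated twice with identical geometry, identical per-neuron
activity and identical optics, differing only in targeting (neurite
$\lambda$ 100 µm vs 20 µm). Every neuron fires independently, so any
inter-ROI correlation is contamination by construction. The default study
conditions are 30 neurons in a 128 × 128 µm field at 1 µm/px, 600 frames at
10 Hz, spontaneous firing at 0.25 Hz, FRCaMPi transduction, wide-field
optics, photon gain 50; these sizes keep the full ten-seed experiment
within a few minutes on one core while leaving ~400 near (<100 µm) pairs
per run. The experiment asserts orderings, not magnitudes: non-targeted raw
near-pair correlation exceeds soma-targeted in every seed; 0.7-subtraction
reduces the non-targeted mean correlation at least 3-fold; soma-targeted
raw correlation lands in the same low range as non-targeted corrected; and
a zero-neuropil control (no neurites, no out-of-focus term) shows no
difference between conditions.

## What the simulations do and do not establish

The generator reproduces the *mechanisms* the analyses are sensitive to —
Hill transduction, exponential transients, exponential expression decay,
shared out-of-focus background, photon noise — under pinned conventions and
seeds. It does not model motion, vasculature, hemodynamics, 3-D optics,
calcium extrusion saturation, or realistic firing statistics. Passing tests
therefore establish that the estimators are correct and calibrated on data
whose generating process is known, and that the contamination orderings
follow from expression geometry and optics alone; they do not certify
absolute in vivo correlation or SNR magnitudes, which depend on unmodeled
tissue properties. Published in vivo medians (ΔF/F₀, SNR, correlation
levels in mice and zebrafish) derive from imaging datasets that are not
reproducible at desk scale and are deliberately not acceptance surfaces;
the package instead verifies every self-contained printed quantity
(titration constants, the $e^{-1}$ = 36.8% point, per-FOV arithmetic such
as 930/16 = 58.125, responsive-fraction arithmetic) and the property-level
claims above.

## Determinism

Every stochastic function takes a seed; compound simulations derive
per-neuron and per-stage sub-seeds deterministically from one master seed
(kept below $2^{31}$). Identical configs and seeds give byte-identical
reports, label images and truth files.
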