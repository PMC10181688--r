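---
title: "Condition-driven VAR connectivity: model, choices, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Condition-driven VAR connectivity: model, choices, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdvar)
```

## The problem

Continuous-wave fNIRS measures cortical hemodynamics through light
attenuation at two near-infrared wavelengths. In a block-design walking
experiment — repeated task blocks separated by standing rests, one footwear
condition per run — the scientific question is *directed*: which cortical
regions drive which, and how does that directed structure change across
conditions relative to a reference (barefoot) condition? `cdvar` answers
this with a vector autoregression whose coefficients are a baseline matrix
plus indicator-weighted per-condition deltas, so that every coefficient has
a direct reading: "the effect of region j at the previous time step on
region i, under condition k, beyond baseline".

## Pipeline and model

**Optical density and the modified Beer–Lambert law.** For each channel,
`optical_density()` computes `ΔOD(t) = −ln(I(t)/Ī)` against the within-run
mean intensity, which makes the result invariant to source power and gain.
`mbll()` then solves, per source–detector pair and time point, the 2×2
linear system relating the two wavelengths' `ΔOD` to `(ΔHbO, ΔHbR)` through
the extinction coefficients, the source–detector distance, and the
differential pathlength factor (DPF). The measurement model fixes neither
the extinction table nor the DPF; the package defaults are the standard
tabulated extinction coefficients at 760/850 nm (in mM⁻¹·cm⁻¹, distances in
cm) and DPF = 6.0, both overridable, and the pipeline log records the
values used. Natural logarithms are used throughout. Since the within-run
mean is the reference intensity, recovered concentrations are centred per
run; only *changes* are interpretable, which is all the VAR uses.

**Filtering.** The hemodynamic band of interest is 10–400 mHz; the package
uses a windowed-sinc (Hamming) linear-phase FIR design of order 71
(72 taps) via `design_fir_bandpass()`. At a 10.2 Hz sampling rate this
yields ≈ 1.00 gain mid-passband (0.2 Hz) and ≈ −82 dB at 2 Hz.
`apply_filter()` applies it forward–backward with odd reflection padding.
Zero-phase application is the single most consequential preprocessing
choice in this package: a one-pass FIR delays every channel by
(order)/2 samples ≈ 3.5 s, and although a *uniform* delay cancels in
cross-channel regressions, mixing filtered and unfiltered quantities or
later non-uniform processing would corrupt the lead–lag structure that
Granger-style estimation relies on. Forward–backward filtering squares the
magnitude response (sharpening the band edges) and cancels phase exactly;
the tests verify a lag-0 cross-correlation peak for an in-band sinusoid.
Whether one filters optical density or hemoglobin is immaterial for a
linear filter and a linear conversion; the pipeline default filters after
conversion (`filter_domain = "hb"`, switchable).

**Low-rank spatial projection.** Connectivity models need trustworthy
signals in every channel; single fNIRS channels often are not. The package
clusters channel coordinates (source–detector midpoints) with K-means
(Euclidean distance, 10 random restarts under one seed, best
within-cluster sum of squares kept) and summarizes each cluster by its
**median** series. The median is preferred to the mean because corrupting
fewer than half the channels of a cluster cannot drag it outside the range
of the intact members, whereas the mean shifts by (corrupted/total) of any
common offset — the tests verify both halves of this statement, and the
robustness study below quantifies it. Even-sized clusters use the mid-pair
average. The default cluster count is M = 6: the montages this package
targets cover three regions of interest (motoric, somatosensory, temporal)
in each hemisphere, and M = 6 reproduces that granularity. M is a free
parameter (`clusters`) and should track the montage, not the data.
Clustering is per montage: runs sharing a geometry share the assignment.

**The condition-driven VAR.** With cluster series `G(t) ∈ R^M`,

$$G(t) = \sum_{\ell=1}^{p} \Phi(\ell)\, G(t-\ell) + \varepsilon_t, \qquad
\Phi(\ell) = \Phi_0(\ell) + \sum_{k=1}^{K} \Phi_k(\ell)\, C_k,$$

with `C_k ∈ {0,1}` constant within a run. The default order is p = 1; the
estimator supports higher p, but long-lag VAR coefficient maps become hard
to read and frequency-domain summaries (e.g. partially directed coherence)
are then more appropriate — deliberately out of scope here. `build_design()`
stacks, per run, the response rows and the lagged predictor blocks
(baseline block plus one indicator-gated block per non-baseline condition),
never forming a lagged predictor across a run boundary. `fit_ols()` solves
all M equations by one shared QR decomposition — runtime linear in the
number of time samples for fixed M — and reports
`Σ̂_ε = EᵀE/(n−q)` and the Wald machinery from
`vec(Φ̂) ~ N(vec(Φ), Σ_ε ⊗ (XᵀX)⁻¹)`. Because each delta block is active
exactly on its own condition's rows, the joint fit decouples: the baseline
estimate equals a VAR fit on baseline data alone, and baseline-plus-delta
equals a fit on that condition alone — a property the tests check to
1e-8. The Kronecker (joint) form of the coefficient covariance is used;
with a shared predictor matrix it coincides equation-wise with per-equation
OLS covariances.

**Inference and maps.** Two-sided p-values come from the standard normal
law of the Wald z statistics. No multiple-testing correction is applied by
default — the per-edge α = 0.05 threshold is the convention in the
per-subject connectivity-map literature this package serves — but
Benjamini–Hochberg step-up is available (`correction = "bh"`; the
in-package implementation is cross-checked against `stats::p.adjust` in the
tests). Self-loops are retained but flagged. Per-condition maps show the
*delta* edges by default, matching the model's parameterization; an
`absolute` mode renders `Φ̂₀ + Φ̂_k` instead, since "the condition's
connectivity" is genuinely ambiguous between the two readings. Hemisphere
tags come from the sign of the centroid x coordinate (x < 0 left,
x > 0 right, x = 0 midline, counted separately), a convention that is
configurable by supplying different coordinates.

**Trials, rests, and sample counts.** By default the pipeline fits task
blocks only, cut from the event markers and trial-averaged within each run
(`E_τ` over trials); rest periods between blocks are short enough that
hemodynamics do not settle, so mixing them into the fitted series would
blur regimes. Trial averaging with four ~22 s trials at 10.2 Hz leaves only
~220 time points per condition, which is why a `per_trial` mode exists that
stacks trials as separate runs instead of averaging them (more samples,
trial-specific noise retained); the fitter warns whenever observations fall
below 10× the per-equation coefficient count. An `include_rest` switch fits
whole runs instead.

## The synthetic-experiment generator

`make_ground_truth()` draws sparse stable coefficient sets: baseline
self-coupling 0.4 on the diagonal, a fraction `sparsity` (default 0.2) of
off-diagonal entries at magnitude `effect_size` (default 0.4, random sign),
and per-condition deltas placed on entries distinct from the baseline
support when possible, all rescaled until every condition's companion
spectral radius is below 0.95. `simulate_experiment()` reproduces the
block paradigm — 17 s initial/final rests, 22 s task blocks, 10 s
inter-block rests, four trials, 10.2 Hz (a 152 s run, 1550 samples) — by
gating the VAR dynamics with a task envelope (boxcar by default; a
canonical-HRF-convolved boxcar is available since real hemodynamics do not
switch instantaneously). Rests carry baseline white noise. Cluster signals
are expanded to five channels per cluster, jittered around six
well-separated scalp-sphere anchors (jitter SD = 1/20 of the minimum
anchor distance, so the spatial clustering is identifiable by
construction), with Gaussian channel noise (SD 0.1 in innovation units),
optional constant-offset outlier channels, and optionally pushed through
the *forward* Beer–Lambert model (HbR set to −HbO/3, a typical
anticorrelation ratio) into two-wavelength intensities so the entire
read→OD→MBLL→filter→project→fit chain is exercised. Student-t innovations
(configurable df) are available to stress the median-vs-mean comparison
beyond the Gaussian case.

What the generator does *not* emulate: physiological nuisance rhythms
(cardiac ~1 Hz, respiration, Mayer waves), motion artifacts, superficial
(short-channel) contamination, and inter-subject variability. Passing
recovery tests on these simulations therefore demonstrates correctness of
the estimator and pipeline plumbing under the model's own assumptions, not
robustness to everything real scalp data contains.

## Numerical choices and degenerate inputs

- OLS via QR; rank deficiency (e.g. a constant channel, a duplicated
  cluster, or a condition with no data) raises a classed error listing the
  collinear columns rather than silently dropping them.
- Zero residual variance (noise-free inputs) produces zero standard
  errors; `wald_pvalues()` flags these as `NA` with a warning instead of
  reporting p = 0.
- The companion spectral radius of every estimated regime is computed and
  reported; estimates at or above 1 trigger a warning. On heavily filtered,
  trial-averaged series the estimated radius legitimately sits near 1 —
  band-pass filtering makes the series very smooth — which is a property of
  the data representation, not an estimation failure.
- K-means uses `stats::kmeans` (Hartigan–Wong, 10 restarts, one seed);
  requesting more clusters than distinct coordinates is an error, and all
  seeded functions restore the caller's RNG state.
- Even-cluster medians average the middle pair; ties need no special
  handling beyond that.
- `fnirs_recording()` rejects nonpositive intensities *before* logarithms
  are taken, naming the offending channel.

## Validation

The test suite and `scripts/acceptance.R` validate the method by property,
at these problem sizes (chosen to make sampling noise small relative to the
margins being tested while keeping a full run in tens of seconds):
coefficient recovery and monotone RMSE over T ∈ {200, 1000, 5000} with 20
replicates of the M = 6, K = 4 design; null calibration of delta
coefficients over 500 replicates at T = 1000 (rejection rate at α = 0.05
expected in [0.03, 0.07]); exact agreement (≤ 1e-8) with an independent
pseudoinverse solve and with a plain VAR(1) in the single-condition
reduction; Beer–Lambert round-trip to ≤ 1e-10 relative error; the FIR
contract (≥ 40 dB at 2 Hz, ±20% at 0.2 Hz, zero-lag cross-correlation
peak); median robustness to one outlier channel in five (median RMSE shift
under 5% of signal SD, mean biased by exactly offset/5); bidirectional
edge detection (both directions of a symmetric 0.4 pair at p ≤ 0.05 in
≥ 95% of 100 replicates at T = 5000); and byte-identical outputs for
identical seed and config. None of these numbers is asserted anywhere
except where the corresponding computation is run.

## Known limitations

- Condition labels attach to whole runs; the design cannot express
  within-run condition switches.
- The asymptotic normal inference ignores small-sample effects; with
  trial-averaged 22 s blocks the per-condition sample count is marginal
  (hence the warning and the per-trial mode).
- Weak stationarity within task blocks is assumed, and heavy filtering
  pushes fitted dynamics toward the unit root; interpret near-unit radii
  as smoothness, but treat radii ≥ 1 with suspicion.
- Per-subject maps only: no group-level inference, no comparison
  statistics across maps.
- The plain-text run format stores full double precision but is not a
  community interchange format; it is meant for this package's own
  round-trips and for assembling runs from other tools' CSV exports.
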