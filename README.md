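# cdvar: condition-driven VAR connectivity for fNIRS

`cdvar` estimates **directed (Granger-causal) effective connectivity**
between cortical regions from multichannel, continuous-wave functional
near-infrared spectroscopy (fNIRS) recordings collected under several
experimental conditions — for example, walking with different footwear,
where a barefoot run serves as the reference. It is aimed at researchers
who have block-design fNIRS runs (one condition per run) and want a
per-condition map of which regions drive which, with Wald p-values per
directed edge.

## The model

Raw two-wavelength light intensities are converted to optical-density
changes and then to oxy-/deoxy-hemoglobin concentration changes via the
modified Beer–Lambert law, band-pass filtered with a zero-phase linear-phase
FIR filter (order 71, 10–400 mHz), and spatially reduced: channels are
clustered by their 3D coordinates with K-means, and each cluster is
summarized by its **median** time series `g_ℓ(t)` (the median tolerates a
minority of low-SNR channels, where a mean would not). The resulting
M-dimensional series `G(t)` is modelled as a vector autoregression whose
coefficients depend on the experimental condition:

    G(t) = Σ_{ℓ=1..p} Φ(ℓ) G(t−ℓ) + ε_t,   ε_t ~ WN(0, Σ_ε)
    Φ(ℓ) = Φ₀(ℓ) + Σ_{k=1..K} Φ_k(ℓ) C_k

with dichotomic condition indicators `C_k`. `Φ₀` is the baseline
connectivity; each `Φ_k` is the connectivity *change* of condition k
relative to baseline. Entry `[i, j]` is the directed effect of cluster j on
cluster i at lag ℓ. Estimation is ordinary least squares on the stacked
lagged design (indicators are constant within a run; lags never cross run
boundaries), and inference uses the asymptotic normal law of the vectorized
coefficients with covariance `Σ_ε ⊗ (XᵀX)⁻¹`. Edges with `p ≤ α`
(default α = 0.05, no multiplicity correction by default) form the
per-condition connectivity maps.

## Worked example

Everything below is synthetic — the package ships a full experiment
simulator (probe geometry, block paradigm, condition-gated VAR dynamics,
channel noise) so the whole pipeline can be exercised without any data
download.

```r
library(cdvar)

truth <- make_ground_truth(M = 6, K = 4, sparsity = 0.2, effect_size = 0.4,
                           seed = 3)
runs  <- lapply(0:4, function(k) simulate_condition_run(truth, k, 5000,
                                                        seed = 10 + k))
fit <- cdvar(runs, condition = c("barefoot", "flat_sole", "medial_wedge",
                                 "personal_shoes", "sgl_shoes"))
fit
#> Condition-driven VAR(1), 6 clusters, baseline 'barefoot' + 4 condition delta(s)
#> Observations per condition: barefoot=4999, flat_sole=4999, medial_wedge=4999,
#>   personal_shoes=4999, sgl_shoes=4999
#> Companion spectral radius: barefoot=0.639, flat_sole=0.841, medial_wedge=0.668,
#>   personal_shoes=0.854, sgl_shoes=0.827

max(abs(fit$phi[["barefoot"]][[1]] - truth$phi0[[1]]))
#> [1] 0.04247234
```

The baseline coefficient matrix is recovered to within ±0.043 of the truth
at T = 5000 samples per condition; the companion spectral radii below 1
confirm every estimated condition regime is stationary. `summary(fit)`
lists the significant directed edges; `build_maps()` turns the fit into
per-condition edge lists with hemisphere tags (sign of the centroid x
coordinate) that export to CSV/JSON/GraphML via `export_map()`.

The full chain — simulate (or read runs written by `write_fnirs()`),
Beer–Lambert, filter, cluster, project, fit, maps — is one call:

```r
res <- run_pipeline(list(seed = 7), out_dir = "out/")
```

which writes `hb/`, `projected/`, `fit/coefficients.csv`, `maps/*.graphml`
and a `log.txt` recording every default used. A thin command-line wrapper
lives at `inst/cli/cdvar-pipeline.R`.

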