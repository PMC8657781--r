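# critmodes

Brain networks near criticality — the balanced regime between global
synchronization and incoherence — show large spontaneous fluctuations of
their overall synchronization level. `critmodes` is an R package for
testing a functional interpretation of those fluctuations: sub-second
windows of **high** synchronization favor integration of information
*within* the network (an internal processing mode), windows of **low**
synchronization leave the network maximally susceptible to *external*
input (an external mode), and the two modes are sharply distinguished only
near the critical point.

It is aimed at computational neuroscientists working with oscillator
network models, band-limited multichannel recordings (EEG-like), or
parcel-level BOLD time series.

## What it computes

**Model.** A network of delay-coupled Stuart-Landau oscillators on a
structural connectome:

```
dz_j = (λ + iω_j − |z_j|²) z_j dt + K Σ_k A_jk (z_k(t − τ_jk) − α z_j) dt + β dW_j
```

with Gaussian natural frequencies (10 ± 0.5 Hz), conduction delays
τ_jk = D_jk / s (s = 7 m/s), diffusive coupling weight α = 0.5, and
Stratonovich-Heun integration at 1 ms decimated to 500 Hz.

**Metrics per 250 ms window (50 ms overlap):**

* order parameter `r(t) = |mean_j exp(iθ_j)|` and its window mean `R`;
* pair correlation function `PCF = N·Var(r)` — the criticality proxy;
* susceptibility `χ = N·Var(r)/⟨r⟩` — external responsiveness;
* symbolic mutual information `SMI` over ordinal patterns
  (m = 3, τ = 14 samples ≈ 28 ms), normalized by log m!, averaged over
  channel pairs, with optional phase-randomized surrogate filtering —
  internal integration;
* topographic similarity `S^amp`: instantaneous Spearman correlation
  between node degree and amplitude — hub dominance.

**Downstream analyses:** dwell-time distributions of hub-dominant periods
(`S^amp > 0`) with maximum-likelihood power-law vs exponential comparison;
wPLI connectivity with epoch-wise binarized degrees; co-activation pattern
(CAP) extraction by k-means with cluster-count selection and a
time-permutation test of per-synchronization-class occurrence rates.

**Synthetic data:** hub-heterogeneous spatially embedded connectomes,
surrogate EEG with a controllable synchronization profile, and parcel
BOLD with planted templates and planted high/low-synchronization
structure, so the entire pipeline is testable offline.

## Worked example

Simulate a 78-node network near its critical coupling and measure the
window-wise correlation structure:

```r
library(critmodes)
conn   <- generate_connectome(n_nodes = 78, density = 0.15, hub_fraction = 0.15, seed = 1)
freqs  <- generate_frequencies(78, mean_hz = 10, sd_hz = 0.5, seed = 7)
params <- sl_params(lam = 0.6, K = 0.4, t_saturate = 15, t_analyze = 30)
sim    <- sl_simulate(conn, freqs, params, seed = 3)
sim
#> Stuart-Landau simulation: 78 nodes, 30.0 s at 500 Hz (lambda = 0.6, K = 0.4)

sync <- order_parameter(sim$phases, fs = sim$fs)
round(c(mean_R = mean(sync$r), PCF = pcf(sync)), 3)
#> mean_R    PCF
#>  0.323  1.784

wm <- window_metrics(sim, sync, degrees = rowSums(conn$adjacency))
round(c(rho_R_smi  = cor(wm$R, wm$smi,   method = "spearman"),
        rho_R_chi  = cor(wm$R, wm$chi,   method = "spearman"),
        rho_R_samp = cor(wm$R, wm$s_amp, method = "spearman")), 3)
#>  rho_R_smi  rho_R_chi rho_R_samp
#>      0.514     -0.666      0.822

table(classify_windows(wm$R, "fixed"))
#>     low neither    high
#>      75      51      23
```

The mean synchronization sits mid-range (0.32) with a large PCF (1.78):
the network is near its transition. Across the 149 windows, higher `R`
goes with higher SMI (ρ = +0.51), lower susceptibility (ρ = −0.67), and
more hub-dominant configurations (ρ = +0.82) — high-synchronization
windows integrate internally while low-synchronization windows are the
responsive ones. Far from the critical coupling these correlations
weaken; `run_model_experiment()` sweeps the coupling grid, locates the
critical K by the PCF maximum, and tabulates exactly this structure per
cell. `run_signal_experiment()` applies the same window pipeline to
multichannel recordings with pooled mean ± 0.5 SD classification, and
`occurrence_permutation_test()` tests which CAPs dominate low- and
high-synchronization volumes in parcel BOLD.

## Package layout

* `R/`, `src/` — implementation (integrator and SMI/Spearman kernels in
  Rcpp);
* `tests/testthat/` — unit, property, and acceptance tests;
* `vignettes/criticality-processing-modes.Rmd` — the model, the metrics,
  the design decisions, and what the synthetic generators do and do not
  emulate.
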