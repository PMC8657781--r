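---
title: "Criticality and internal/external processing modes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Criticality and internal/external processing modes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The scientific question

A brain network operating near criticality -- the balanced regime between
global order (synchronization) and disorder (incoherence) -- exhibits large
spontaneous fluctuations of its overall synchronization level. `critmodes`
implements a simulation-and-analysis pipeline built around one hypothesis
about what those fluctuations are *for*: sub-second temporal windows of
high synchronization favor integration of information *within* the network
(an internal mode), while windows of low synchronization leave the network
maximally susceptible to *external* input (an external mode), and this
division of labor is sharp only near the critical point.

The package provides (i) a delay-coupled Stuart-Landau oscillator model on
a structural connectome, (ii) window-wise metrics quantifying
synchronization, internal integration, external susceptibility, and
functional network configuration, (iii) dwell-time heavy-tail analysis,
(iv) a parcel-level co-activation pattern (CAP) analysis for BOLD-like
data, and (v) synthetic generators that make every stage testable without
any external download.

# The network model

Each of the $N$ network nodes is a Stuart-Landau oscillator -- the normal
form of a supercritical Hopf bifurcation -- coupled through the binary
structural adjacency $A_{jk}$ with axonal conduction delays:

$$
\dot z_j = \left(\lambda + i\omega_j - |z_j|^2\right) z_j
  + K \sum_k A_{jk}\left(z_k(t - \tau_{jk}) - \alpha z_j\right)
  + \beta \xi_j(t)
$$

* $\lambda$ (dimensionless, homogeneous): distance from the Hopf
  bifurcation. Uncoupled, a node settles on a limit cycle of radius
  $\sqrt\lambda$ for $\lambda > 0$ and on a damped focus for
  $\lambda < 0$ -- the two closed-form limits the test suite checks.
* $\omega_j$: natural angular frequency, drawn from
  $\mathcal N(10, 0.5^2)$ Hz (the dominant rhythm of resting human EEG)
  and converted to rad/s; non-positive draws are redrawn rather than
  clipped to preserve approximate normality.
* $K$ (dimensionless, homogeneous): coupling strength, the swept control
  parameter.
* $\alpha \in [0,1]$: diffusive-coupling weight, interpolating between
  direct synaptic-like input ($\alpha = 0$) and gap-junction-like exchange
  ($\alpha = 1$); default 0.5.
* $\tau_{jk} = D_{jk}/s$: conduction delay from the inter-node distance
  $D_{jk}$ (mm) at speed $s = 7$ m/s, so millimetre distances give
  millisecond delays. Delays are rounded to the nearest integration step
  (error at most $dt/2$, far below the ~100 ms oscillation period).
* $\beta = 0.05$: standard deviation of complex Gaussian white noise,
  entering both quadrature components independently as
  $\beta\sqrt{dt}\,\mathcal N(0,1)$ per step.

## Numerical scheme

Integration uses the Stratonovich-Heun predictor-corrector at
$dt = 1$ ms, with the *same* Wiener increment added in the predictor and
the corrected update. Delayed states are read from a ring buffer; the
history before $t = 0$ holds the random initial state (drawn uniformly on
the complex unit disc under the run seed), a choice washed out by the 15 s
saturation period that is discarded before analysis. Output is decimated
to 500 Hz. The corrector stage evaluates delayed terms at $t + dt$; for
zero-delay edges the predictor state substitutes for the (unknown) future
state. Halving $dt$ changes the time-averaged order parameter by less
than 2% on a 20-node test network, and noiseless runs are bit-for-bit
reproducible at fixed $dt$ and seed. Non-finite states abort with an
error naming the $(\lambda, K)$ cell.

# Window-wise metrics

**Order parameter.** $r(t)e^{i\psi(t)} = N^{-1}\sum_j e^{i\theta_j(t)}$.
Model phases are $\arg z_j$; sensor-like signals use the analytic-signal
angle after zero-phase band-pass filtering (4-12 Hz default). This phase
convention is fixed here once and reused by every module.

**Pair correlation function.** $\mathrm{PCF} = N(\langle r^2\rangle -
\langle r\rangle^2)$, the criticality proxy: synchronization variance
peaks at the critical coupling.

**Windows.** 250 ms windows with 50 ms overlap (stride 200 ms), anchored
at the first sample with the final partial window dropped. Windows are
classified `low`/`neither`/`high` either by fixed thresholds
($R < 0.3$ / $R > 0.5$, the model convention) or by pooled thresholds
$\langle R\rangle \pm 0.5\,\mathrm{SD}$ computed across all windows,
subjects, and conditions (the sensor convention).

**Susceptibility.** $\chi = N(\langle r^2\rangle - \langle r\rangle^2) /
\langle r\rangle$ from the raw within-window moments of $r(t)$; it is the
window's PCF normalized by its mean synchronization and proxies
responsiveness to perturbation.

**Symbolic mutual information.** Signals are mapped to ordinal patterns
of $m = 3$ samples separated by $\tau = 14$ samples (28 ms at 500 Hz,
resolving up to $f_s/(m\tau) \approx 11.9$ Hz); the lag is rescaled in
time units for other sampling rates. SMI is the plug-in mutual
information of the joint pattern distribution normalized by $\log m!$,
averaged over all channel pairs per window. Rank ties are broken by
temporal order; being rank-based, SMI is invariant under strictly
monotone amplitude transforms. For sensor-like data, pairs failing a
two-sided Wilcoxon rank-sum comparison (window-wise real values vs 20
phase-randomized surrogates, $p < 0.01$) are excluded from the average;
model runs skip the filter, since the question there is the raw
correlation structure, not channel-level significance.

**Topographic similarity.** $S^{\mathrm{amp}}(t)$ is the Spearman
correlation between node degree (structural row sums for the model;
epoch-averaged degrees of the binarized wPLI network for sensor data) and
the instantaneous amplitude vector, averaged per window. Positive values
flag hub-dominant configurations. wPLI matrices are computed per 30 s
epoch with 5 s overlap and binarized at the top 30% of off-diagonal
values, ties resolved by stable pair-index order; a vanishing imaginary
cross-spectrum gives wPLI 0 by convention (no detectable lagged
interaction).

## Locating the critical coupling

`run_model_experiment()` sweeps $K$ at fixed $\lambda$, averages the PCF
over seeds, and takes the critical $K$ as the maximum of a 3-point moving
average of the PCF across the grid. The smoothing is a peak-localization
choice: with a handful of seeds the seed-averaged PCF is a noisy estimate
of a smooth curve, and a raw argmax can land on a fluctuation several
grid steps from the transition. At the desk-scale defaults (78 nodes,
$\lambda = 0.6$, 20 couplings, 5 seeds, 30 s per run) the correlations of
window-wise $R$ with SMI (positive), $\chi$ (negative), and
$S^{\mathrm{amp}}$ (positive) are all strongest near the PCF maximum and
weaker at both sweep ends -- the sign/peak structure that the acceptance
suite checks.

# Dwell-time analysis

Dwell times are the lengths of maximal runs with $S^{\mathrm{amp}}(t) >
0$; runs touching either series boundary are censored (their length is
only a lower bound) and discarded. The tail $x \ge x_{\min}$ (default
200 ms, the time scale of the window dynamics) is fitted by maximum
likelihood to a continuous power law $p(x) \propto x^{-\beta}$
($\hat\beta = 1 + n / \sum \ln(x_i/x_{\min})$) and to a shifted-support
exponential, and the models are compared by the loglikelihood ratio
$R_L$ (positive favoring the power law) with the standard normalized
ratio test ($p = \mathrm{erfc}(|R_L| / \sigma\sqrt{2n})$). $x_{\min}$ is
fixed rather than estimated: the scientific question is whether the tail
is heavy, not where it begins. Recovery at $n = 2000$ shows exponent bias
below 0.05, and the sign of $R_L$ classifies power-law vs exponential
truth with more than 95% accuracy at $n = 5000$.

# Co-activation pattern analysis

Parcel-level volumes (volumes x parcels) pooled across conditions and
subjects are clustered by k-means with Euclidean distance and multiple
restarts. The cluster count is selected by the index
$(CC + UU)/(2\,CU)$, the ratio of mean inter-group similarities (inverse
Euclidean distance between per-group CAP occurrence-rate vectors) within
conscious-like pairs, within unresponsive-like pairs, and across; the
index is 1 when all groups are identical and peaks at the planted count
on synthetic data with group-level variability.

Volume-wise synchronization applies the order parameter across parcels to
analytic-signal phases of each parcel's linearly detrended time course;
volumes are classified `low`/`neither`/`high` by the pooled
mean $\pm 0.5$ SD rule. Per class, each CAP's occurrence rate is compared
with a null built by uniform time permutations of the label series
(20,000 by default; the label multiset, and hence the null marginals, are
preserved exactly). CAPs above the one-sided $1 - \alpha$ null quantile
($\alpha = 0.005$, the 99.5th percentile) are flagged dominant. Volumes
in the `neither` band take part in the permutation pool but are tested in
neither class.

# What the synthetic generators emulate -- and what they do not

* `generate_connectome()` builds a connected, spatially embedded graph
  with designated hubs (degree at least twice the median) in a 150 mm
  box. It reproduces the two features downstream analyses rely on --
  degree heterogeneity and mm-scale distances -- but none of the
  anatomy, modular organization, or inter-subject variability of a real
  tractography network. Default density 0.15 and hub fraction 0.15 are
  plausible placeholders, not estimates of any particular connectome.
* `generate_surrogate_eeg()` mixes a shared band-limited source into
  independent band-limited sources with a time-varying weight tracking
  the requested synchronization profile. It captures controllable global
  synchronization fluctuation in a band, which is all the sensor-side
  stages assume; it has no volume conduction, no spatial topography, and
  no 1/f background. Because a pure shared source is annihilated by
  common-average re-referencing, surrogate recordings should be analyzed
  with `rereference = FALSE`.
* `generate_parcel_bold()` renders one template per volume plus an
  oscillatory synchronization component and noise: during high-class
  blocks all parcels share a spatially uniform common oscillation
  (co-activation); during low-class blocks each parcel oscillates with
  its own phase (mixed sign across space). This makes the volume-wise
  synchronization classifier separate the classes while k-means still
  recovers the templates. Template labels persist for short runs so that
  parcel time courses are smooth enough for analytic-signal phases. With
  `sync_strength = 0` and `noise_sd = 0` every volume equals its
  template exactly. Hemodynamics, motion, and physiological nuisance
  structure are not modeled.

Passing tests on these generators therefore demonstrates the
correctness and internal consistency of the *methods*, not any property
of real EEG or fMRI recordings.

# Numerical choices and degenerate inputs

* Histogram bins are anchored at 0 with right-open edges (widths 0.02
  for SMI, 0.1 for $\chi$); counts conserve the number of windows.
* $\chi$ is `NA` when a window's mean $r$ is 0; $S^{\mathrm{amp}}$ is
  `NA` for a constant degree vector; a window whose SMI pairs are all
  filtered out reports `NA`.
* Spearman correlations use average ranks for ties throughout.
* wPLI binarization retains exactly $\lceil 0.3\,n_{\text{pairs}}\rceil$
  pairs per epoch, ties broken by pair index for reproducibility.
* Classification thresholds that eliminate both extreme classes warn
  rather than stop.
* All generators and drivers are deterministic under their seed
  arguments; sweeps derive per-run seeds from a single master seed.

# Problem sizes

The package's reference analyses are desk-scale by design: the sweep runs
$\lambda = 0.6$ with 20 couplings, 5 frequency seeds, and 30 s of
analyzed signal per run on a 78-node synthetic connectome; heavy-tail
recovery uses $n = 2000$-$5000$ samples; the CAP pipeline uses 600
volumes of 90 parcels with 2000 permutations. These sizes were chosen so
that every result in the test suite and acceptance script is recomputed
from scratch at run time while the full pipeline remains reproducible on
a single CPU.

# Known limitations

* Only homogeneous $\lambda$ and $K$ are supported; no heterogeneous or
  fitted parameter maps.
* The model analyses use structural degrees directly; inferring degrees
  from model-side wPLI is not implemented.
* Multiple-band analyses are independent reruns without joint
  multiple-comparison correction; low/high comparisons are reported as
  pairwise rank tests.
* $x_{\min}$ selection by distance minimization and alternative
  heavy-tail families (lognormal, truncated power law) are out of scope.
* Voxel-level fMRI, source localization, and acquisition-specific
  preprocessing are out of scope; the CAP machinery is
  dimension-agnostic and operates on parcels.
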