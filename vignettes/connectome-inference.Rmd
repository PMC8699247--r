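---
title: "Inferring functional connectomes from calcium fluorescence traces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring functional connectomes from calcium fluorescence traces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

`fluoroconn` treats a two-photon recording as a neurons × frames matrix of
baseline-normalized fluorescence `C` (dF/F0) generated, per neuron, by an
AR(1) indicator responding to a non-negative spike train:

    c(t) = γ · c(t−1) + s(t),     C(t) = c(t) + ε(t),   ε iid Gaussian.

Inference inverts this generative model and then asks which neuron pairs
co-vary beyond what the rest of the recorded population explains:

1. **Deconvolution** solves, per neuron,
   `min ½‖c − C‖² + λ Σ s(t)` subject to `s(t) = c(t) − γ c(t−1) ≥ 0`,
   by an online active-set sweep over "pools" (a pool-adjacent-violators
   scheme): each frame starts as its own pool, and adjacent pools merge
   whenever the later pool's fitted height falls below the decayed
   continuation of the earlier one, which would imply a negative spike at
   the boundary. The sweep is exact for this convex program and linear-time
   per trace, which is what keeps whole-recording deconvolution cheap. The
   implementation is in C++ (`src/oasis.cpp`); a box-constrained
   quasi-Newton optimizer serves as an independent oracle in the test
   suite, together with a KKT check of the returned solution (tolerance
   1e-6 on toy instances).
2. **Thresholding** zeroes entries of the deconvolved train below
   Θᵢ = μᵢ + α·σᵢ, with μᵢ and σᵢ the sample mean and standard deviation
   (n−1 denominator) of neuron i's amplitudes over *all* frames, zeros
   included. Survivors pass through unchanged, so thresholding is a masked
   copy and the nonzero count is non-increasing in α.
3. **Smoothing** convolves each row with the symmetric five-frame kernel
   (1/3, 2/3, 1, 2/3, 1/3). Imaging frames (20 ms at 50 Hz) are long
   relative to synaptic delays, yet causally coupled firing still lands a
   frame or two apart; smearing each spike across ±2 frames makes that
   co-firing visible to the zero-lag covariance of the next stage. The
   weights are deliberately not normalized: partial correlations are
   invariant to per-neuron scale.
4. **Partial correlations** come from the precision matrix Φ = Σ⁻¹ of the
   smoothed activity (frames as observations):
   p_ij = −Φ_ij / √(Φ_ii Φ_jj), diagonal set to 0. Conditioning on all
   other recorded neurons suppresses edges induced by shared presynaptic
   drive. Edges are ranked by |p_ij| with deterministic lexicographic
   tie-breaking.

The assumptions worth keeping in mind: a single AR(1) decay per neuron
(no baseline drift, no AR(2) rise time), additive white measurement noise,
excitatory-only coupling (the non-negativity constraint discards inhibitory
responses), and enough frames relative to neurons for Σ to be estimated.

# Parameters

| Parameter | Default | Units | Role |
|---|---|---|---|
| `gamma` | `"auto"` | per frame | indicator decay; estimated per neuron from the lag-2/lag-1 autocovariance ratio, which is robust to white noise (the lag-0 term is the one noise inflates). Falls back to 0.95 with a warning when a trace carries no usable autocorrelation. |
| `lambda` | 0 | dF/F0 amplitude | sparsity penalty. Kept at 0 because the pipeline's own thresholding stage is the designated noise filter; `min_spike = 1e-6 × max(trace)` only clears numerically negligible output. |
| `alpha` | 2 | standard deviations | thresholding strength. AUROC declines slowly with α while AUPR peaks near 2–3, so 2 is the default; the α-sweep is insensitive to the n vs n−1 choice in σᵢ at realistic frame counts. |
| kernel | (1/3, 2/3, 1, 2/3, 1/3) | — | smoothing weights; configurable because slower imaging warrants more center-heavy weights. Validity requires odd length, symmetry, maximal center. |
| `ridge` | 0 | fraction of mean(diag Σ) | starting regularization for the inversion; escalated automatically (see below). |

# The simulator

`generateNetwork` draws directed Erdős–Rényi networks with an exact edge
count `round(density · n(n−1))`, or undirected Watts–Strogatz small-world
networks via igraph. `simulateSpikes` is a discrete-time conditionally
Poisson model: neuron j's intensity in frame t is
`firing_rate/frame_rate + coupling · Σᵢ A(i,j) · s(i, t−1)`, clipped to
[0, 1] (a warning fires if clipping touches more than 10% of
neuron-frames). `renderFluorescence` applies the AR(1) recursion and adds
iid Gaussian noise. Defaults mirror the study conditions the package
targets: 50 Hz imaging, 0.1 Hz baseline firing, indicator decay 0.5 s,
noise sd 0.2 (the last two are conventional choices for a GCaMP-class
indicator at moderate SNR, exposed as configuration rather than asserted
as faithful to any particular dataset).

`coupling_strength` defaults to 0.1. The relevant stability quantity is
the branching ratio `coupling · density · (n−1)` (expected direct
offspring per spike); 0.1 keeps a 60-neuron, density-0.1 network
subcritical at ≈ 0.6. Experiments on larger networks in this package set
`coupling = 0.5 / (density · (n−1))` for the same reason — a supercritical
network saturates the intensity clip and stops resembling cortical
activity.

What the simulator deliberately omits: light-scattering / neuropil
crosstalk between neighboring neurons (which produces *correlated*
low-amplitude noise in real recordings), inhibitory neurons, short-term
synaptic depression, baseline drift, and optical effects. Consequently,
recovery results on simulated data show that the pipeline correctly
inverts its own generative assumptions — they do not certify performance
on real recordings, where the omitted effects are exactly the ones that
stress the method.

One visible consequence: on this simulator the binarization ablation
(`binarizeSpikes`, all nonzero amplitudes set to 1) does not degrade
accuracy relative to raw deconvolved amplitudes — with strictly lag-1
coupling and iid noise, binarization equalizes jitter-split amplitudes and
acts as a weak implicit smoother, while its amplification of noise spikes
is only an unbiased dilution. With richer noise (e.g. noise sd 0.5, or
correlated crosstalk) binarization hurts, which is the behavior reported
on realistic simulations and the reason the pipeline retains amplitudes.
The full conditioning (threshold + smooth) dominates both variants by a
wide margin in every configuration we compute in the test suite.

# Numerical choices

- **Singular covariance.** Duplicated rows, silent neurons, or fewer
  frames than neurons make Σ singular. `precisionMatrix` escalates a
  ridge `r · mean(diag Σ) · I` through 0, 1e-8, 1e-6, … until the inverse
  is finite, reporting each escalation and recording the value used in the
  `Connectome`. Silent neurons (all-zero rows after thresholding) are
  excluded *before* the covariance step and their pairs reported as 0 —
  exclusion keeps results deterministic where jittering would not.
- **Thresholding degeneracy.** A zero-variance row gets Θᵢ = μᵢ, so a
  constant row passes through; the case is reported via `message()`.
- **Smoothing boundaries.** Frames beyond either end are treated as zero —
  the natural resting value for sparse spike trains; the kernel is never
  renormalized at the edges.
- **Percentile thresholds** use R's default linear-interpolation sample
  quantile; ties at the cutoff survive (≥ comparison), consistent with the
  ≥ in the main thresholding rule.
- **Partial-correlation overshoot.** |p| may exceed 1 by rounding; up to
  1e-8 is clipped, anything larger is an error (it indicates an invalid
  precision matrix, not rounding).
- **Scoring.** The confusion sweep processes tied scores as a block.
  Trapezoidal integration of the ROC then equals the Mann–Whitney
  concordance count with ties at half weight (property-tested on small
  instances). The PR curve uses step interpolation — precision held at the
  block value across its recall increment — avoiding the optimistic linear
  interpolation between PR points. Ground truth is symmetrized before
  scoring because partial correlations are undirected; a pair counts once
  even when reciprocal connections exist.

# Design choices that were genuinely open

- Thresholding statistics include zero frames (the literal reading of
  "mean and standard deviation of xᵢ"); excluding zeros would make Θᵢ
  track only the firing amplitudes and zero out far more activity.
- The stage order is threshold **then** smooth: smoothing first would
  smear sub-threshold noise into super-threshold mass and partially defeat
  the filter.
- Ranking uses |p_ij|; the signed coefficient is kept in the `Connectome`
  for inspection, since strong negative partial correlations are
  informative even though the simulator only generates excitation.
- The deconvolver sits behind the `deconvolveAll` surface and other spike
  inference methods can be substituted upstream of `thresholdSpikes`
  without touching the rest of the pipeline.

# Problem sizes

The test suite and calibration script run entirely on simulated data: the
recovery and ablation checks use 60 neurons × 30,000 frames (600 s at
50 Hz) over 5 seeds, the missing-neuron experiment 150 neurons with
subsamples of 150/90/60 × 3 replicates, and the scoring calibrations a
100-neuron truth with 200 random rankings. These sizes give stable
stochastic estimates (SEMs well inside the asserted margins) while keeping
a full run in the low minutes on one CPU; the pipeline itself scales to
thousands of neurons, with the Σ inversion's cubic cost the eventual
bottleneck.

# Known limitations

- No directionality: partial correlations are symmetric, and frame
  intervals exceed spike-timing scales anyway.
- Inhibition is invisible to the non-negative deconvolution contract.
- The AR(1) kernel ignores indicator rise time (AR(2)); traces from slow
  indicators at high frame rates will deconvolve with timing bias.
- Hidden neurons can induce spurious edges between their common targets;
  the missing-neuron experiment quantifies the degradation but the method
  does not correct for it.
- No significance thresholding of p_ij into a binary graph (graphical
  lasso and related sparse precision estimators are out of scope); the
  output is a ranking.
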