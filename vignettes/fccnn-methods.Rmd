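---
title: "Frequency-attention CNN for EEG depression classification, and its entropy-based interpretation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Frequency-attention CNN for EEG depression classification, and its entropy-based interpretation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Resting-state EEG carries class-discriminative rhythm information in major
depressive disorder (MDD): depressed subjects show elevated overall spectral
power and a shifted dominant rhythm relative to healthy controls. `fccnn`
implements a complete desk-scale pipeline around that observation:

1. a **synthetic-EEG cohort generator** whose two classes differ by
   configurable spectral signatures, so the whole pipeline can be exercised
   and tested without clinical recordings;
2. a **frequency channel-based CNN (FCCNN)**: a deliberately small
   convolutional classifier whose first block weights each EEG channel by
   its own mean FFT power — a parameter-free, per-segment attention
   mechanism driven by brain rhythm rather than learned weights;
3. an **interpretation pipeline** that asks what input pattern each channel
   of the trained network responds to most strongly (activation
   maximization), and then scores the complexity of those patterns by
   Shannon entropy over *adaptive* partitions obtained from affinity
   propagation (AP) clustering, projected onto the 10–20 scalp montage and
   five anatomical regions.

## The classifier

A recording is cut into non-overlapping 1,024-sample windows (4 s at
256 Hz). Each 20 × 1024 window is reshaped channel-wise, row-major, into a
20 × 32 × 32 tensor; the reshape is exactly invertible and the ordering is
a documented convention (the network is agnostic to any fixed invertible
layout).

The forward pass is:

    attention → dropout → conv(32@3×3, ReLU) → conv(64@3×3, ReLU)
              → flatten → FC(128, sigmoid) → FC(32, sigmoid) → FC(1, sigmoid)

**Attention block.** For each channel the mean power over the
positive-frequency FFT bins (DC excluded, up to Nyquist) is computed from
the segment itself, min–max mapped onto [0.1, 1], and used as a scalar
multiplier on that channel's plane. Properties that follow directly and are
tested: the weights are scale-covariant (a common amplitude rescaling of all
channels leaves them unchanged), permutation-equivariant, order-preserving
in channel power, and the block is the identity when all channels carry
equal power. With the block disabled the model is the without-attention
ablation. Two conventions are fixed here: the (0.1, 1) weight range is
realised as the closed interval that min–max mapping attains at its
endpoints, and the power average runs to the Nyquist frequency (128 Hz at
fs = 256) — the widest band the sampling rate supports.

**Training.** Binary cross-entropy, momentum SGD (lr 0.01, momentum 0.9,
decay 1e-4, Nesterov), batch size 80, He initialisation, input dropout 0.25,
an 80/20 stratified train/validation split inside the training subjects, and
per-epoch history. The architecture contains no batch-norm layer; 80 is the
mini-batch size. Exact conv/FC widths and the loss are conventions chosen
small (the design goal is as few layers as possible) and are all
configurable in `model_config()` / `train_config()`.

One numerical-conditioning step is applied: inputs are divided by a single
global RMS factor estimated from the training set. Because it is one common
constant across channels, the attention weights are unchanged (scale
covariance); it only keeps sigmoid/ReLU pre-activations in a trainable range
regardless of the physical amplitude scale (microvolts).

Prediction thresholds the sigmoid output at 0.5, ties going to the positive
(MDD) class — a fixed convention for reproducibility.

## The synthetic generator

Each class is a `spectral_class_profile`: a list of narrow-band peaks
(frequency Hz, amplitude µV, bandwidth Hz), a 1/f^a background exponent, a
noise SD (µV), and a total-power multiplier. Defaults encode the reference
conditions the generator emulates: the healthy class peaks near **3.015 Hz
and 22.11 Hz**, the MDD class near **7.035 Hz** with an overall power
elevation. Only the direction
of the elevation is established; its magnitude is a free parameter with
default `power_scale = 1.5` (amplitudes scale by √1.5). Peaks are sinusoids
with per-channel uniform frequency jitter inside the bandwidth (default
0.5 Hz, so periodogram peaks stay within ±0.25 Hz of nominal) and i.i.d.
phases; the background is spectrally shaped white noise with a = 1, the
standard EEG-like 1/f form. The default montage is the 19 electrodes of the
five-region map plus **A2** (right ear lobe) as the 20th channel — a documented,
overridable choice, since standard 19-electrode 10–20 montages leave the
20th channel open. A2 belongs to no cortical region and is excluded from
region means.

What the generator does *not* emulate: artifacts, eye blinks,
non-stationarity, volume conduction, inter-channel covariance. Passing tests
therefore demonstrate correctness of the pipeline mechanics and
recoverability of spectral class structure — not clinical performance on
real EEG.

## The interpretation pipeline

**Activation maximization.** For each input channel c, the package
maximizes the summed ReLU response of all first-layer filters restricted to
channel c's plane (all other channels zero), over the sphere ‖x‖₂ = ρ
(default ρ = 1; the scale is arbitrary for *ranking* channels). The outcome
is one 32 × 32 matrix per channel; summing the first conv layer's filter
responses restricted to that channel is the documented unit aggregation. The optimizer is projected gradient ascent with
backtracking (steps that would lower the objective are halved and retried),
so the objective is non-decreasing across accepted steps; it stops when the
accepted displacement falls below `move_tolerance` or at `max_iter`. The
λ‖x‖² regulariser is available but defaults to 0 because the hard norm
constraint already bounds the input. On a linear unit the method recovers
the closed form ρ·w/‖w‖ to 1e-6; on a toy ReLU net it matches dense random
sphere search (10⁵ draws) within 1%.

**Adaptive-partition entropy.** Each channel's activation matrix is
flattened to 1,024 values, sorted ascending, and clustered with affinity
propagation on similarities s(i,k) = −(vᵢ−vₖ)². Clusters become partitions
with center C = (Zmax+Zmin)/2 and radius R = |Zmax−Zmin|/2; the dividing
coordinate between adjacent partitions is the lower partition's upper edge
plus half the inter-partition gap (the gap midpoint). Shannon entropy in
bits over the partition occupancy probabilities is the channel's score:
it reflects how the activation values distribute over *distinct modes*,
rather than assuming a uniform distribution as the equal-width-bin baseline
(`uniform_bin_entropy()`) does.

Three numerical choices deserve explanation, because message passing on
1-D data with many near-duplicate values is degenerate:

* **Damping escalation.** At the textbook damping of 0.5, AP oscillates
  indefinitely on large tight clusters (the reference implementation in
  scikit-learn shows the identical failure). `partition_entropy()` starts
  at damping 0.9 and escalates to 0.95 and 0.98 if message passing fails to
  converge or collapses to all-singleton exemplars.
* **Preference ladder with separation scoring.** The number of emergent
  clusters depends on the preference (the diagonal of the similarity
  matrix), and no single quantile works across balanced, unbalanced, and
  multi-modal data: the conventional median fragments an unbalanced pair of
  tight clusters, while the minimum over-merges small neighbouring
  clusters. The package therefore runs AP at a ladder of preference
  quantiles {0, .05, .1, .25, .5, .75, .9}, scores each candidate partition by
  (minimum inter-partition gap)/(maximum partition radius), and keeps the
  best-scoring candidate provided that ratio exceeds 1.5. If no candidate
  shows genuinely separated structure, the series is treated as a single
  mode with entropy 0. This realises the intended contract exactly —
  partition entropy equals known-membership entropy whenever clusters are
  separated by ≥ 10× their internal spread (at 10× separation the
  gap/radius ratio is about 2) — and makes the estimate affine-invariant,
  since all similarities and their quantiles scale together.
* **Quantile skeleton.** For series longer than 256 values the exemplar
  search runs on a deterministic quantile-spaced subset; every value is
  then assigned to its nearest exemplar before probabilities are computed.
  This caps the O(N²) message-passing cost on 1,024-value activation
  series and is exact for separated clusters.

Overlapping adjacent partitions (possible under arbitrary assignments) are
merged with a warning rather than raising an error, so the entropy is always
defined. `ap_cluster()` itself keeps the plain single-run contract (median
preference, configurable damping, non-convergence flag) and matches
scikit-learn's exemplars and assignments exactly on separated 1-D instances.

**Regions and topography.** Per-channel entropies are averaged over five
anatomical regions (frontal: Fp1, Fp2, F3, F4; left temporal: F7, T3, T5;
central: C3, C4, Fz, Cz, Pz; right temporal: F8, T4, T6; occipital: P3, P4,
O1, O2). Scalp maps are rendered by inverse-distance weighting at channel
level and piecewise-constant nearest-electrode colouring at region level.
Entropies are reported as single model-level values (not per class); the
per-class question is left to the user by interpreting models trained on
single-class subsets.

## Evaluation

`confusion_metrics()` uses MDD (label 1) as the positive class.
`roc_auc()` computes the Mann–Whitney AUC (ties count ½) with a fixed score
direction, so inverted labels give AUC 0 rather than being silently
re-oriented. `cross_validate()` assigns segments of the training subjects to
stratified folds (class balance preserved; the held-out test subjects are
evaluated once, by the final model). `pvalue_matrix()` uses Welch's
unequal-variance t-test for every pair of approaches — fold variances
generally differ between architectures — with a symmetric matrix, an `NA`
diagonal, and the conventions p = 1 (both samples constant and equal) and
p = 0 (both constant, different).

## Problem sizes used by the tests and the acceptance script

The package's own verification runs at desk scale, chosen as the smallest
sizes at which every claim is meaningful: unit tests use a miniature
4-channel, 32 Hz cohort with 8 × 8 tensors; the end-to-end checks use the
full-fidelity configuration (20 channels, 256 Hz, 20 subjects per class,
60 s per subject, 600 segments, 20 × 32 × 32 tensors) trained for 15
epochs, which is where held-out accuracy on the default profiles saturates;
the attention ablation repeats that over 5 seeds. The acceptance script
trains the default model for 15 epochs with and without attention on one
seeded cohort and runs the full interpretation pipeline.

## Known limitations

* The synthetic classes are far more separable than clinical EEG; reported
  synthetic accuracies say nothing about patient-level performance.
* Activation maximization optimises one channel at a time with the other
  planes at zero; cross-channel interactions of the first layer are not
  probed.
* AP clustering is quadratic in the skeleton size; the skeleton cap trades
  a small amount of partition resolution for bounded runtime.
* Entropy 0 is returned for unimodal activation distributions by design;
  channels are distinguished only when their activation values form
  separated modes.
* The EDF writer/reader supports continuous 16-bit recordings with a single
  sampling rate — enough for round-tripping cohorts, not a general EDF+
  implementation.
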