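---
title: "Decoding motor imagery with gahtnet: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding motor imagery with gahtnet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gahtnet)
```

## The decoding problem

Imagined movement (motor imagery, MI) attenuates the 8–30 Hz sensorimotor
rhythm over the cortical representation of the imagined effector — the
event-related desynchronisation (ERD). Left-hand imagery attenuates power over
the right motor cortex (electrode C4), right-hand imagery over the left (C3),
foot imagery over the vertex (Cz). A decoder therefore has to combine three
kinds of structure: the *spatial* arrangement of electrodes on the scalp, the
*spectral* content of each channel, and the *temporal* evolution of the trial.
`gahtnet` implements a network that addresses each in turn and trains it
natively in R.

Trials enter as (trials × channels × time) arrays at 250 Hz. The canonical
epoch spans 4.5 s starting 0.5 s before the cue, i.e. 250 × 4.5 = 1125
samples; the only preprocessing is per-channel z-scoring
(`zscore_channels()`), with population variance (no n−1 correction) and
statistics always taken from the training partition so the test set never
influences them. We chose per-partition statistics over per-trial scaling
because it is the least leaky reading of "standardise each channel"; per-trial
scaling would also erase between-trial power differences, which are exactly
the signal.

## The GATE block

**Graph construction.** Electrodes are nodes; edges connect physically
adjacent electrodes. The adjacency rule is `A_ij = 1` iff `i = j` or
`{i,j}` is an edge. Symmetric normalisation is then applied literally as
`Â = D̃^{-1/2}(A + I)D̃^{-1/2}` with `D̃` the degree matrix of `A + I` — note
that because `A` already carries a unit diagonal, the self-weight entering the
degree is 2. Both conventions (single or double self-loop) give a valid
operator with spectrum in (−1, 1] and top eigenvalue exactly 1; we implement
the double-loop form because that is what the adjacency rule and the
normalisation formula compose to when read literally.
The shipped 22-electrode montage's edge list was generated once by Delaunay
triangulation of the azimuthal-equidistant projected 10-10 positions —
deterministic, physiologically local, and checked in the test suite against an
independent brute-force circumcircle triangulation. The 3-electrode montage is
the C3–Cz–C4 chain.

**Chebyshev graph convolution.** Each time step's channel vector is filtered
with `Z_t = Σ_{k<K} w_k T_k(Â) X_t`, `K = 3`, using the recursion
`T_0 = I`, `T_1 = Â`, `T_k = 2ÂT_{k-1} − T_{k-2}` evaluated at `Â` directly
(not at a rescaled Laplacian — the operator already has unit spectral radius,
so the Chebyshev argument is already well-scaled). One scalar weight per
order keeps one graph-feature map, so the electrode axis survives: this is the
only reading under which the following stages (a depthwise spatial kernel
spanning exactly C electrodes, and channel attention over electrodes) are
composable, and it is the interpretation we fixed for the ambiguous
feature-dimension notation.

**SE channel attention** squeezes each electrode to its temporal mean,
passes the C-vector through a bottleneck (`ReLU`, then `sigmoid`; reduction
ratio 4, at least one hidden unit) and rescales electrodes by the resulting
(0, 1) gate. With the gate bypassed (`Z' = Z`) one obtains the
"without channel attention" ablation exactly.

**Temporal–spatial encoder.** Three EEGNet-style stages: (1) 16 shared
temporal filters of length 64 with batch normalisation; (2) a depthwise
spatial kernel spanning all C electrodes with multiplier 2 (→ 32 maps), batch
norm, ELU, average pooling by 8; (3) a length-16 separable temporal
convolution (depthwise + pointwise), batch norm, ELU, average pooling by 7,
dropout 0.3. Both temporal convolutions use same-padding, which is the only
convention under which the canonical arithmetic 1125 → 140 → 20 holds; the
output length is `T' = floor(floor(T/8)/7)`. Batch-norm uses momentum 0.99
and epsilon 1e-3, the compact-EEG-model convention.

## The HADTE block

**Residual ECA.** `F_eca = F + ECA(F)`: the 32-map descriptor (global average
over time) is filtered by a kernel-3 1-D convolution across neighbouring maps
(the adaptive ECA kernel rule gives k = 3 at 32 maps) and squashed to a
(0, 1) gate; the gated copy is added residually, so zero weights give exactly
`1.5 F`.

**Local masked attention.** Multi-head self-attention (2 heads × dimension 8)
whose pre-softmax scores receive the additive mask `M_ij = 0` iff
`|i − j| ≤ w·d` (window `w = 16`, dilation `d = 1`), else a −1e9 sentinel.
Because the inner dimension (16) is smaller than the 32-dim features, Q/K/V
project 32→16 and the output projects 16→32 so the residual adds in feature
space — the only consistent reading of "two heads of dimension 8" on 32-dim
features. The local stage takes its input raw; only the global stage is
preceded by layer normalisation, exactly as the two stages are defined. No
positional encoding is used anywhere (none is specified); temporal order is
carried by the convolutions, and the global stage is therefore
permutation-equivariant — a property the tests assert rather than a defect.

**Global attention** is pre-LN multi-head attention over the full sequence
with a residual from the un-normalised input.

**TCN.** Two residual blocks of causal dilated convolutions (kernel 4,
dilations 1 and 2, 32 filters, ELU, dropout 0.3), chosen as the
attention-TCN family convention since the block shape is otherwise
unspecified. The classifier consumes the last-position feature vector rather
than a flatten of the whole sequence; with a causal stack the last position
is the only one whose receptive field covers the entire sequence, which makes
it the natural summary (this was an open choice and is our documented
resolution).

## Classifier, loss, training

A dense layer maps the 32-vector to class logits, softmax to probabilities,
and the mean cross-entropy (probabilities clipped at 1e-12) is minimised with
Adam at learning rate 0.001, batch size 64, up to 1000 epochs with
early-stopping patience 300. The early-stopping schedule fixes a patience but leaves the monitored
quantity open; we hold out a stratified 20% of the training trials and
monitor validation accuracy — monitoring the test set would leak; the
best-epoch weights (and batch-norm running statistics) are restored. One
integer seed controls the holdout draw, shuffling, weight initialisation and
dropout, giving bit-identical runs on a single device.

All forward and backward passes are written explicitly (R orchestration with
compiled Armadillo kernels for the long temporal convolutions); the analytic
gradients of every parameter are verified against central finite differences
in the test suite at tolerance 1e-4.

## Ablation switchboard

Seven ablated variants are constructible by flag: without channel attention; without the temporal–spatial encoder; without
residual ECA; without local masked attention; without global attention;
without both attention stages; without the whole HADTE block. Flags remove
the stage's parameters entirely. Two bypass wirings needed explicit
definitions: (a) without the encoder, the SE-gated graph sequence is
average-pooled by 56 (= 8 × 7) so it arrives at the same `T' = 20` the
attention geometry expects, with C-dim features; (b) without HADTE, the
classifier consumes the last position of `F_GATE` — the same summary
convention as the TCN path, keeping the two bypasses comparable.

## The synthetic generator

`generate_trials()` emulates what the decoder exploits, not scalp
biophysics. Each trial is (a) per-channel pink (1/f) noise plus one shared
pink source mixed across electrodes with weights decaying in scalp distance
(a crude volume-conduction surrogate), plus (b) an amplitude-modulated 11 Hz
sinusoidal rhythm on every electrode. The trial's class attenuates the rhythm
amplitude on its ERD electrodes (left hand → C4, right hand → C3, feet → Cz,
tongue → bilateral C3+C4 at half strength) by the configured factor. Rhythm
amplitude is calibrated per channel so the stated `snr_db` is the band-limited
8–13 Hz power ratio against that channel's noise; the defaults (6 dB, 250 Hz,
4.5 s epochs, 72 trials/class, mild log-normal per-subject gain and noise
variation) are what we consider a realistic, clearly-above-floor operating
point. What the generator does *not* contain: eye/muscle artifacts,
non-stationary drifts, inter-channel covariance beyond the shared source,
or realistic ERD time-courses. Passing tests on this data therefore
demonstrate that the implementation learns spatial band-power structure —
the mechanism the architecture targets — not that it attains any particular
accuracy on real recordings.

A nearest-centroid classifier on log band power at the ERD electrodes
(`bandpower_oracle_classify()`) serves as an independent reference: it is a
ceiling on noise-free configurations, sits at chance on null configurations,
and its accuracy is monotone in the configured attenuation.

## Numerical choices and degenerate inputs

* Mask sentinel: −1e9 added to logits (a true −Inf would poison softmax
  backpropagation); a fully masked row is an error, not a NaN.
* Softmax and cross-entropy are max-shifted / clipped for stability.
* Wilcoxon signed-rank: zeros dropped, average ranks for ties; the exact null
  distribution for n ≤ 25 is computed by the generating-polynomial recursion
  on doubled ranks (so half-integer average ranks stay exact), two-sided
  p = 2·min(P≤, P≥) capped at 1; above 25, normal approximation with tie and
  continuity corrections. With nine subjects the exact path is the one that
  matters.
* Kappa of a single-cell confusion matrix (expected agreement 1) is defined
  as 0 with a warning; zero-variance channels abort z-scoring with the
  channel named.
* Epoch windows are half-open `[cue − t_pre, cue + t_post)` with 0-based
  sample indices; epochs crossing a recording boundary are dropped with a
  warning rather than zero-padded.

## Problem sizes used in the shipped checks

The test suite and `scripts/acceptance.R` exercise the full-size geometry
(22 × 1125 inputs, 20 × 32 features) for shape and ablation checks, and train
the full model on a 3-electrode, 200-trial, strongly separable two-class
synthetic set (attenuation 0.9, 6 dB) for up to 100 epochs — a deliberately
scaled-down stand-in for session-scale training that a laptop CPU completes
in minutes. Unit tests use further-shrunken block configurations (the
architecture is size-generic) so that each oracle comparison runs in seconds.

## Known limitations

* The GDF reader/writer implements a documented subset of the GDF 2.x layout
  sufficient for cue-based MI pipelines and round-trips its own files; it is
  not a full biosig implementation.
* Trial caches and checkpoints use single-file RDS containers.
* Training is single-device CPU; there is no hyperparameter search, no
  multi-map graph features (`d_g > 1`), and no learned adjacency — the graph
  is fixed by the montage.
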