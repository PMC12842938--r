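---
title: "Dynamic multimodal fusion for audio-visual time series: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dynamic multimodal fusion for audio-visual time series: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynfuse)
```

This vignette is the package's account of its own methods: the model it
implements, the assumptions behind it, the parameters that matter, what the
synthetic data generator does and does not emulate, and the numerical design
choices made where the design was genuinely open.

## 1. The model

A sample is a pair of feature sequences — audio `T_a × D_a` and video
`T_v × D_v`, rows indexed by time — with a binary label; class 1 is the
positive ("case") class everywhere, which fixes the orientation of
precision, recall and F1.

### Multi-scale temporal experts (per modality)

Each modality matrix is split into univariate channels. Every channel is
sliced twice by sliding windows:

* **long scale**: patch length `P_L`, stride `Str_L` (defaults 16/16),
* **short scale**: patch length `P_S`, stride `Str_S` (defaults 4/1),

giving `N = ⌊(L − P)/Str⌋ + 1` patches; trailing steps not covered by a full
window are dropped, because the count formula is exact only under flooring.
The patch-to-stride resolution `R = P/Str` quantifies overlap; the config
validator enforces `R_long < R_short` — the long scale is coarse and the
short scale dense. (The defaults give `R_long = 1`, `R_short = 4`.)

Long patches are linearly embedded into `d_model` and processed by a
**selective state-space block**: LayerNorm → linear expansion to
`hidden_dim` → causal depthwise convolution (kernel `conv_kernel`, left
padding so no future leakage) → SiLU → per-step parameters
`Δ = softplus(Linear)`, `B = Linear`, `C = Linear` → selective scan →
SiLU-gated projection back to `d_model` with a residual connection. The scan
is the input-dependent recurrence

$$h_t = \bar A_t \odot h_{t-1} + \bar B_t x_t, \qquad y_t = \langle C_t, h_t \rangle,$$

with zero-order-hold discretisation $\bar A_t = \exp(\Delta_t \otimes A)$
and Euler input rule $\bar B_t = \Delta_t \otimes B_t$. The readout is taken
from the *state* (`y_t = C_t · h_t`); a readout of the input alone would
make the recurrence irrelevant.

Short patches are embedded, given learnable positional encodings, and
processed by a stack of **local-window transformer** layers: pre-norm
multi-head self-attention restricted to the symmetric band
`|i − j| ≤ ⌊w/2⌋`, then a pre-norm GELU feed-forward network, each with a
residual connection. Stacking `l` layers grows the receptive field to about
`l·w`.

A **long-short router** per modality computes a global context vector
(time-mean of the raw channel followed by a linear map) and a two-way
softmax `[p_L, p_S]`; the fused representation is
`concat(p_L · z_L, p_S · z_S)` along the sequence dimension — exactly
`N_L + N_S` tokens. Per-channel fused matrices are averaged across a
modality's channels (see §4).

### Two-level dynamic fusion

A light audio encoder (depthwise convolution, SiLU, global average pooling,
linear map to a 512-d descriptor) feeds a path gate
(Linear 512→`gate_hidden` → ReLU → Dropout 0.2 → Linear →4 → softmax) that
selects exactly one **modality-level expert**:

| path | inputs | nominal cost |
|---|---|---|
| E1 | audio only | 0.6 GFLOPs |
| E2 | audio + compressed video | 1.0 |
| E3 | audio + full video | 1.6 |
| E4 | audio + full video, deep fusion | 2.3 |

At inference the default policy is the confidence-threshold branching: with
confidence above 0.75 take the argmax, except that a non-audio argmax with
confidence at or below 0.9 is bumped one tier up (`min(p+1, 4)`); below the
bar, path 2 if the audio-only score exceeds 0.4, else path 4. A plain-argmax
policy is available via `path_policy = "argmax"`; both are implemented
because the two rules serve different deployment profiles (the thresholded
rule buys insurance on borderline samples).

The selected expert's token matrix then passes through `n_units` **fusion
units**, each selecting one of four operations: O1 audio-internal weighted
aggregation (provably no cross-modal input), O2 gated single-head
cross-attention at reduced width (`d/4`), O3 bidirectional 4-head
cross-attention with residuals, O4 a three-level co-attention stack closed
by a self-attention decoder block. Time-mean pooling and a linear softmax
head produce the class probabilities.

### Training

Discrete selections are relaxed with Gumbel-Softmax samples
$\tilde g_k = \mathrm{softmax}\big((\log\pi_k + b_k)/\tau\big)$, where
$\pi_k$ are the gate's pre-softmax logits and $b_k \sim$ Gumbel(0,1); the
argmax branch executes, and a straight-through scale routes its gradient
into the soft probability. Because the argmax of `(logits + b)/τ` does not
depend on τ, hard selection frequencies are exactly
categorical(softmax(logits)) — the calibration the acceptance suite checks.
The temperature anneals geometrically from `tau_start` (5.0) to `tau_end`
(0.1) across the epoch budget.

The loss is the resource-aware objective

$$L = L_{task} + \lambda\Big(\sum_i p_i\,C(E_i) + \sum_j\sum_k \pi_{j,k}\,C(O_k)\Big),$$

with the *probabilities* (not the hard selections) weighting the costs, so
the penalty is differentiable. `L_task` is cross-entropy by default; the
focal variant $-\alpha_y (1-p_y)^\gamma \log p_y$ (γ = 2, α = inverse class
frequency) is available for imbalanced data. Optimisation is Adam
(lr 1e-4, batch 16 by default), early stopping on validation loss with
patience 15 within at most 120 epochs, all randomness fixed by the config
seed (default 42). Validation and test always use hard decisions, so early
stopping tracks deployable behaviour. Data are split by sample id with
largest-remainder apportionment of the 7:1:2 default ratios, which
guarantees subject-level separation whenever ids identify subjects.

## 2. Parameters that matter

| parameter | default | units / meaning |
|---|---|---|
| `patch_long_len/stride` | 16 / 16 | time steps; `R_long = 1` (non-overlapping) |
| `patch_short_len/stride` | 4 / 1 | time steps; `R_short = 4` |
| `mamba_hidden`, `mamba_state`, `mamba_conv_kernel` | 1024, 16, 4 | scan width, state dim per hidden channel, causal kernel; a state dimension of 10 is reachable via config |
| `lwt_heads`, `lwt_head_dim`, `lwt_ff_dim` | 8, 64, 2048 | attention geometry |
| `lwt_window` (`w`), `lwt_layers` (`l`) | 5, 2 | window width in steps and stack depth; no canonical values exist for these, so the defaults are package choices sized for sequences of a few dozen to a few hundred steps |
| `lambda` | 0.01 | weight of the expected-cost penalty; no canonical value exists — 0.01 makes the penalty comparable to late-training task loss without dominating early learning |
| `tau_start`, `tau_end` | 5.0, 0.1 | Gumbel temperature endpoints |
| `lr`, `batch_size`, `patience`, `max_epochs`, `seed` | 1e-4, 16, 15, 120, 42 | optimiser settings |

Costs `C(E_i)` default to the nominal tier values 0.6/1.0/1.6/2.3 GFLOPs.
The fusion-operation costs have no canonical published values; the package
uses the nominal tiers 0.05/0.12/0.25/0.45 GFLOPs, chosen strictly
increasing with roughly the same ratio ladder as the expert tiers — the
loss only consumes relative magnitudes. An analytic alternative (the
package's elementary-op counter, which is additive over sub-modules and
strictly increasing across both tiers by construction) is available via
`cost_mode = "analytic"`.

## 3. The synthetic generator

`generate_dataset()` emulates the *shape* of behavioural feature streams —
by default 25 audio channels (a typical low-level-descriptor count) and 136
video channels (68 landmark coordinate pairs) — and plants a two-scale class
signal:

* **Trend** (positives only): a linear ramp of amplitude `trend_strength`
  plus a slow sinusoid (period ≈ T, amplitude 0.3 × trend) on a seeded
  subset of ⌈D/4⌉ channels. Negatives have zero slope.
* **Fluctuation**: a high-frequency sinusoid (period 4–8 steps) of
  amplitude 0.5 × `fluctuation_strength` on another seeded channel subset;
  positives get three seeded burst windows (length ≈ T/8) with tripled
  envelope, negatives a flat envelope.
* i.i.d. Gaussian noise of sd `noise_sd` everywhere; the uninformative
  modality is pure noise.

The two components are deliberately matched to the two experts: the ramp is
invisible inside a 4-step window, the bursts are invisible to a 16-step
non-overlapping average. Channel subsets and periods are dataset-level
(drawn once per call), phases and burst positions per-sample; generation is
a pure function of the config.

What the generator does **not** emulate: cross-channel correlation
structure of real descriptor banks, heavy-tailed noise, tracking dropouts
correlated with expression, label noise, or subject-level repeated
measures. Tests passing on this generator therefore demonstrate that the
architecture and optimisation behave as designed — signal at the planted
scale is found, routing adapts, cost pressure works — not that any
particular clinical accuracy would be attained on real corpora.

Perturbation protocols mirror the robustness methodology: additive Gaussian
noise per modality; truncation (keep the first `⌈(1−rate)·T⌉` rows);
resampling, interpreted as down-then-up linear interpolation so information
is lost while the evaluated shape is preserved; shuffling of a seeded
fraction of row indices; zeroing of a seeded fraction of rows; and modality
masking on whole time steps (matching frame-level tracking dropout), with
zero or per-feature-mean imputation. Generative "optimal recovery" of
masked content is out of scope.

## 4. Numerical and design choices

* **State matrix.** The scan's `A` is diagonal per hidden channel,
  parameterised `A = −exp(a_log)` with `a_log` initialised to
  `log(1..state_dim)` and trainable (freezable by flag). Negative-real
  diagonal dynamics guarantee `|Ā| < 1` for any positive Δ, hence bounded
  states on bounded inputs.
* **Scan schedule.** `selective_scan()` evaluates the recurrence
  sequentially with vectorised per-step updates; a parallel associative
  schedule would be an optimisation, not a semantic change, and correctness
  is defined by the literal `scan_oracle()` (agreement to 1e-5 max-abs is
  enforced in tests; observed agreement is at round-off).
* **Banded attention.** The additive −1e9 mask convention defines the
  semantics (`band_mask()` exposes it); the implementation computes each
  query row over its band only. The two are bit-identical — after row-max
  subtraction the excluded terms underflow to exactly zero — and the banded
  evaluation keeps the per-layer elementary-op count linear in `N` at fixed
  `w`, which the op-counter tests assert.
* **Window symmetry.** The attention window is centred (truncated at the
  edges), not causal: this is a whole-sequence classification task, and a
  surrounding context is the natural reading. No causality is claimed for
  the short-range expert.
* **Channel handling.** The temporal experts are applied per univariate
  channel and the fused token matrices averaged (`channel_mode =
  "per_channel"`), keeping the token count independent of `D_m`; a pooled
  mode first averages channels into one series and runs a single pipeline,
  trading channel resolution for a `D_m`-fold cost reduction. One router per
  modality, shared across channels.
* **Gradient machinery.** All blocks run on the package's reverse-mode
  autodiff engine; attention, scan, convolution and layer norm are fused
  nodes with hand-derived backward passes, validated against central finite
  differences (1e-3 relative on the full block, ~1e-10 on primitives).
* **Compressed video path.** "Compression" is a fixed seeded Gaussian
  projection of the feature dimension to `max(8, D/4)` scaled by `1/√m`
  (norm-preserving in expectation); no reconstruction step follows, because
  reconstruction would add cost to a pathway whose purpose is cheapness.
* **Expert internals.** Only the cost tiers and input sets of E1–E4 are
  canonical; the internals here are a shared skeleton (self-attention
  encoders, plus 1 bidirectional cross-attention layer for E3 and 3 for
  E4) chosen so the analytic op counts are strictly increasing across the
  tiers, which the tests enforce rather than assume.
* **Fusion gate.** A single global gating head emits all `n_units`
  decisions from pooled concatenated modality features (`n_units = 4` by
  default).
* **Tie-breaks and degenerate inputs.** Argmax ties break to the lowest
  index. Empty datasets, empty splits, non-finite inputs, rate/σ outside
  range, patches longer than the series, positional tables outgrown by the
  sequence, all-masked modalities under mean imputation, and non-one-hot
  hard decisions are rejected with errors naming the violated contract.
  Probabilities are clamped at 1e-12 before logs; softmaxes subtract the
  row max.
* **Precision/recall orientation.** Metrics are positive-class; UA (macro
  recall) and WF1 (support-weighted F1) carry the macro view. A predictor
  that never predicts positive yields precision 0 with an explicit
  `undefined_precision` flag rather than NaN.
* **Significance.** `significance_compare()` uses the pooled-variance
  two-sided t-test with Cohen's d from the pooled SD and Bonferroni
  adjustment `min(1, p·n)`; pooled rather than Welch so that the test
  statistic and the effect size share one variance estimate.

## 5. Problem sizes used by the shipped studies

The test-suite and acceptance-script studies run end-to-end training at
small scale, chosen so the whole suite completes comfortably on one CPU:
400 samples of 32 × 4 per modality, `d_model = 8`, pooled channel mode,
2 fusion units, 6–10 epochs, Adam at 5e-3, five seed repeats for the
routing-adaptation and cost-pressure properties. These sizes are the
package's own study conditions for its verifiable claims; the architecture
itself scales to the default configuration (256-d model, 1024-wide scan)
without code changes, only compute.

## 6. Known limitations

* **The long-short router tracks contribution, not scale semantics.**
  Because the fused representation concatenates `N_L` long tokens with
  `N_S` short tokens along the sequence and the classifier pools them by
  time-mean, the gradient on `[p_L, p_S]` rewards whichever stream
  contributes more to the pooled mean; with dense short-scale patching
  (`N_S ≫ N_L`) that is usually the short stream, whatever scale the class
  signal lives at. At the small scales of the shipped studies the trained
  router therefore should be read as a learned mixing weight, not as a
  diagnosis of the signal's time scale. The tests assert what holds:
  normalization, end-to-end gradient flow, and substantial movement of the
  mixing weights during training.
* Pure-R training is practical for the small studies above but slow for
  corpus-scale work; the engine is single-threaded and allocates per-node.
* The parallel (associative) scan schedule is not implemented; long-scale
  sequences are processed in linear time but serially.
* The synthetic generator's independence assumptions (see §3) mean
  robustness numbers computed on it should not be quoted as expectations
  for real recordings.
* Text modalities, pretrained feature extraction, and generative recovery
  of missing modalities are out of scope; inputs are assumed to be
  already-extracted numeric feature sequences.
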