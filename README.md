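# dynfuse

Dynamic multimodal fusion networks for audio-visual time-series
classification, in pure R.

## The problem

Behavioural screening for depression increasingly relies on non-verbal cues
extracted from recordings: frame-level acoustic descriptors (pitch, energy,
MFCCs, or pooled deep embeddings) paired with facial geometry, action-unit,
gaze and head-pose tracks. Two properties of such data make off-the-shelf
sequence classifiers a poor fit:

1. **The class signal lives at two temporal scales.** Slow, session-long
   drifts (flattened prosody, reduced expressiveness) coexist with
   short-lived fluctuations (bursty speech-rate changes, brief facial
   events), and which scale matters varies per subject.
2. **Not every sample deserves the same computation.** Many recordings are
   classifiable from audio alone; spending a deep audio-visual fusion stack
   on all of them wastes most of the budget, while a fixed cheap model fails
   the ambiguous minority.

`dynfuse` implements an architecture that addresses both, end to end:

* **Multi-scale temporal experts per modality.** Each univariate channel is
  sliced into long-range patches (patch length `P_L`, stride `Str_L`) and
  short-range patches (`P_S`, `Str_S`); the patch-to-stride resolution
  `R = P/Str` is lower for the long scale. Long patches feed a **selective
  state-space (Mamba-style) block** — an input-dependent linear recurrence
  `h_t = Ā_t ⊙ h_{t-1} + B̄_t x_t`, `y_t = ⟨C_t, h_t⟩`, with `Ā, B̄, C`
  derived from the input at each step and evaluated by a linear-time scan.
  Short patches feed a **local-window transformer** whose self-attention is
  banded (`|i−j| ≤ ⌊w/2⌋`). A two-way softmax router, conditioned on a
  global-context pooling of the raw channel, weights the two encodings
  (`[p_L, p_S] = softmax(W z_B + b)`) before they are concatenated along the
  sequence dimension.
* **Two-level dynamic fusion.** A light audio encoder feeds a path gate that
  selects exactly one of four modality-level experts of increasing cost —
  audio-only (0.6 GFLOPs nominal), audio + compressed video (1.0),
  audio + full video (1.6), deep audio-visual fusion (2.3) — using either a
  plain argmax or the confidence-threshold policy (thresholds 0.75 / 0.9 /
  0.4). A stack of fusion units then each selects one of four fusion
  operations (audio-internal aggregation, gated single-head cross-attention
  at reduced width, bidirectional multi-head cross-attention, or a deep
  co-attention stack). Only selected sub-networks execute.
* **Resource-aware training.** Discrete decisions are relaxed with
  Gumbel-Softmax samples at an annealed temperature and trained with
  straight-through gradients; the loss is
  `L = L_task + λ (Σ_i p_i C(E_i) + Σ_j Σ_k π_{j,k} C(O_k))`, so gate
  probabilities feel the expected cost of what they select. Cross-entropy
  and focal loss (for class imbalance) are both available.

Everything runs on a compact reverse-mode automatic-differentiation engine
built into the package (`R/autodiff.R`), with fused hand-derived backward
passes for the scan, banded/dense attention, convolution and layer norm —
no external deep-learning runtime is required.

The package also ships the surrounding study apparatus: a synthetic
two-modality generator with controllable trend/fluctuation signal, noise,
informative modality and class imbalance; perturbation protocols (Gaussian
noise, truncation, resampling, shuffling, missing values, modality masking
with zero/mean imputation); the six standard metrics (accuracy, precision,
recall, F1, unweighted accuracy, weighted F1); pooled t-test comparison with
Cohen's d and Bonferroni correction; robustness sweeps; computation-path
usage reports; and attention-map export.

## Worked example

Train a small model on synthetic data whose label is carried by a slow trend
in the audio stream while the video stream is pure noise:

```r
library(dynfuse)

data_cfg <- generator_config(
  n_samples = 400, T_a = 32, D_a = 4, T_v = 32, D_v = 4,
  trend_strength = 1.5, fluctuation_strength = 0,
  informative_modality = "audio", noise_sd = 0.3, seed = 11)
samples <- generate_dataset(data_cfg)

cfg <- run_config(
  d_model = 8, patch_long_len = 16, patch_long_stride = 16,
  patch_short_len = 4, patch_short_stride = 2,
  mamba_hidden = 16, mamba_state = 4, mamba_conv_kernel = 2,
  lwt_heads = 2, lwt_head_dim = 4, lwt_ff_dim = 16, lwt_window = 5,
  lwt_layers = 1, router_dim = 8, channel_mode = "pooled",
  n_units = 2, gate_hidden = 32, lambda = 0.01, lr = 5e-3,
  batch_size = 16, max_epochs = 10, patience = 4, seed = 42)

fit <- train_model(samples, cfg, verbose = TRUE)

names(samples) <- vapply(samples, function(s) s$sample_id, character(1))
test_set <- samples[fit$split$test]
pred <- predict_model(fit, test_set)
print(compute_metrics(pred$label, pred$pred))

pd <- path_distribution(fit, test_set)
print(round(pd$fractions, 3))
cat(sprintf("mean nominal cost: %.2f GFLOPs/sample\n", pd$mean_nominal_cost))
```

Output (about 45 s on one CPU core):

```
epoch   0  task 0.6858  cost 1.510  tau 5.000  val 0.6145 acc 1.000
epoch   1  task 0.3119  cost 0.902  tau 3.237  val 0.0193 acc 1.000
...
epoch   9  task 0.0004  cost 0.700  tau 0.100  val 0.0073 acc 1.000
accuracy 1.0000  precision 1.0000  recall 1.0000  f1 1.0000  ua 1.0000  wf1 1.0000  (n = 80)
path1 path2 path3 path4 
    1     0     0     0 
mean nominal cost: 0.70 GFLOPs/sample
```

Reading the numbers: the per-epoch lines show the task loss, the expected
decision cost (in nominal GFLOPs) and the annealed Gumbel temperature; the
cost falls from 1.51 to 0.70 as the gates learn that the video stream is
uninformative. The trained model classifies the held-out split perfectly and
routes **every** test sample through the cheapest, audio-only path
(fraction 1 on path 1), paying 0.6 GFLOPs for the expert plus 2 × 0.05 for
the two audio-internal fusion units — conditional computation doing exactly
what the resource-aware loss asks of it.

A shell interface with the same functionality (plus perturbation and
significance-comparison subcommands) is installed at
`system.file("cli", "dynfuse", package = "dynfuse")`.

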