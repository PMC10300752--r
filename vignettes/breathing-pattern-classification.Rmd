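---
title: "Classifying breathing patterns from wearable NIRS signals with a 1D pre-activation ResNet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying breathing patterns from wearable NIRS signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nirsnet)
```

## The problem

Wearable near-infrared spectroscopy (NIRS) devices measure changes in
oxygenated (O2Hb) and deoxygenated (HHb) haemoglobin concentration in the
tissue under the probe. Placed on the chest, the slow hemodynamic
oscillation that respiration imprints on these signals carries enough
information to distinguish breathing regimes that matter clinically:
relaxed breathing, labored (loaded) breathing of the kind produced by a
resistance trainer to emulate dyspnea, and rapid/shallow breathing at 25
breaths/min emulating tachypnea. `nirsnet` classifies short windows of
such signals — 64 samples at 10 Hz, i.e. 6.4 s — into these three
conditions with a one-dimensional convolutional residual network, so that
a monitoring system can label each incoming 6.4-s stretch in real time
without any hand-crafted feature extraction.

## The model

The classifier is a pre-activation residual network adapted to 1D
signals. Its elementary unit is the bottleneck residual unit

$$x_{l+1} = F(x_l, W_l) + x_l,$$

where the residual function $F$ applies batch normalization, ReLU and a
convolution three times (1x1 narrowing, 1xk spatial, 1x1 widening), each
batch norm and ReLU *preceding* its convolution. When the input and
output shapes agree the shortcut is the identity, so a unit whose final
convolution has zero weights passes its input through exactly — the
property that keeps very deep networks trainable, and one of this
package's invariant tests.

The layout, front to back:

* **Stage 0** — a plain 1x5 convolution to 16 channels, stride 1, taking
  the raw (normalized) window.
* **Stage 1** — the size-reducing front unit: one bottleneck residual
  unit (1x1, 1xk, 1x1, all 16 channels) whose first convolution has
  stride 2, halving the 64-sample input to 32 while forming features
  with a wider receptive field than plain downsampling. The spatial
  kernel k is 5 (`stage1_k5`, the best variant) or 3 (`stage1_k3`). The
  control variant `ds` removes this stage entirely and instead feeds the
  network inputs halved by decimation (`downsample_windows()`).
* **Stages 2–4** — 12 bottleneck units each, with widths (16, 16, 64),
  (32, 32, 128) and (64, 64, 256); the first unit of Stages 3 and 4
  carries stride 2 in its first convolution. Lengths therefore run
  64 → 32 → 32 → 16 → 8.
* **Head** — a final batch norm + ReLU, global average pooling over the
  temporal axis (8 → 1, 256 features), and a fully connected layer to
  the 3 class logits.

Counting convolutional and fully connected layers only, the default
`stage1_k5` network has 1 + 3 + 108 + 1 = 113 weighted layers.

Where a unit changes shape (Stage 1, and the first unit of Stages 2–4)
the shortcut is a 1x1 projection convolution with matching stride,
applied to the pre-activated input — the standard convention for this
network family; the architecture description itself does not fix the
projection type. Convolutions carry no bias (redundant before batch
norm); the classifier keeps its bias. Weights are He fan-in initialised;
batch-norm scale starts at 1 and shift at 0.

### Parameter and FLOP accounting

`layer_account()` tabulates every layer's parameters and forward-pass
FLOPs (2 per multiply–accumulate, convolutions and classifier only,
batch norm / ReLU / pooling excluded). The headline totals follow a
**main-path convention**: the four projection-shortcut convolutions are
tabulated but excluded from the totals. This is a deliberate,
documented choice — it is the only convention that reproduces both
published figures for this architecture, 0.7 M parameters and 15 M
FLOPs at input length 64 (including projections gives 0.76 M and
15.9 M). Both views are printed, and `include_shortcuts = TRUE` switches
the totals.

## Training recipe

`train_config()` defaults encode the study's recipe: SGD with momentum
0.9, batch size 64 (final partial batch kept), 120 epochs, cross-entropy
loss, initial learning rate 0.1 divided by 10 every 30 epochs. Epochs
are 0-based, so drops land exactly at epochs 30, 60 and 90 —
`lr_at_epoch()` is the single source of truth and the logged history is
checked against it. Weight decay is unstated in the source description;
the package defaults to 1e-4, the convention of this network family,
applied to all trainable parameters and recorded in the fitted object.
Evaluation uses the final-epoch model; no early stopping, augmentation
or class weighting is applied anywhere. Whether repeated runs should
re-draw the train/test split or only the initialisation is likewise not
specified; `run_experiment()` re-draws both by default
(`resplit = FALSE` fixes the split).

Everything is seeded: the same seed and data reproduce the weight
initialisation, the shuffling order, every per-epoch history row and the
final weights bit for bit. The engine is written directly on BLAS matrix
products (im2col convolutions, channels-first activations), runs
single-threaded, and backpropagation is verified against central finite
differences in the test suite at relative error below 1e-7.

### Input preprocessing

Windows are per-window, per-channel zero-mean normalized by default.
The raw signals are concentration *changes* with arbitrary slow offsets,
so removing each window's mean discards the uninformative operating
point while preserving oscillation amplitude — which carries class
information (loaded breathing has the largest amplitude). No variance
scaling is applied, and `normalize = FALSE` turns the step off; the
choice is stored in the fitted object and re-applied by `predict()`.
Channel order is fixed and documented: O2Hb first, HHb second. THb and
TSI are refused as model inputs (`select_channels()` raises an
"excluded by design" error) because they are deterministic functions of
O2Hb and HHb.

## Windowing and splits

`crop_windows()` tiles a recording left-to-right at stride 64 (6.4 s,
non-overlapping — our reading of windows "taken at 6.4-s intervals");
overlap is available via the `stride` argument but off by default. A
trailing remainder shorter than one window is discarded, so a 3-min
recording at 10 Hz yields exactly floor(1800/64) = 28 windows.
Recordings with movement artifacts are handled by an explicit JSON
exclusion mask (sample ranges to drop) rather than any automatic
detector: the removal criterion in the source protocol is unstated, so
the package performs none silently.

`split_windows()` implements two protocols. The stratified 80:20 split
draws `ceiling(0.8 * n)` training windows *within each class* — the
only rounding convention consistent with all three published per-class
counts (531 → 425, 780 → 624, 874 → 700). The subject-level split
assigns whole subjects (ceiling again: 17 of 21 train), guaranteeing no
subject contributes windows to both sides — the stricter protocol for
generalisation claims.

## The synthetic generator

The study's recordings are not redistributable with the package, so
`simulate_recording()` emulates the qualitative structure of the three
conditions: a quasi-periodic breathing oscillation whose per-breath rate
and amplitude are drawn around condition means, on top of a slow
sinusoidal drift and white sensor noise, with HHb generated anti-phase
at 0.4x the O2Hb amplitude (O2Hb has the higher signal-to-noise ratio
of the two; the ratio asserts no physiology). The waveform adds a fixed
0.2-weight second harmonic so the classes are not linearly separable
from a single sinusoid coefficient.

Defaults (editable in `default_condition_params()`): baseline 14
breaths/min at amplitude 1.0, loaded 12 breaths/min at amplitude 2.5,
rapid/shallow 25 breaths/min at amplitude 0.5; drift period 60 s,
amplitude 0.5; noise s.d. 0.1. Only the 25 breaths/min rapid rate and
the orderings — loaded has the largest amplitude, rapid the shortest
period — are study-defined; every other number is a package choice made
once to reproduce those orderings at a realistic signal-to-noise ratio.
Per-breath jitter is nowhere specified; we use 1 breath/min rate jitter
and 15% amplitude jitter, enough variability that windows from one
recording are not near-duplicates.

What the generator deliberately does **not** emulate: cardiac
pulsation, Mayer waves, motion artifacts, inter-subject baseline
differences, or the absolute concentration scales of real devices.
Passing the synthetic acceptance checks therefore demonstrates that the
architecture, training loop and evaluation machinery work end to end on
signals with the right statistical structure — it does not certify the
published real-data accuracies, which require the original recordings.

As a learnability floor, `periodogram_oracle()` fits a two-threshold
baseline (dominant frequency separates rapid from slow; peak-to-peak
amplitude separates loaded from baseline). On generator defaults this
floor exceeds 95%, and the acceptance suite requires the trained
`stage1_k5` network to beat both 95% and that floor on held-out
windows.

## Numerical choices and degenerate inputs

* Batch-norm epsilon 1e-5; running statistics updated with rate 0.1 and
  used at inference, so prediction is deterministic. Very short
  trainings (a handful of updates) leave running statistics far from
  the batch statistics — inference accuracy then lags training
  accuracy, which is expected behaviour, not a defect.
* Logit ties resolve to the lowest class index (`baseline` first).
* Sub-unit-variance guards: batch variance is clamped at 0; per-breath
  rates are clamped at one tenth of the mean rate, amplitudes at 0.
* A window longer than its recording yields an empty window set, not an
  error; an empty training set, out-of-range labels and shape
  mismatches raise immediately.
* Empty test classes give *undefined* (NA) recall, never silent zeros,
  and balanced accuracy refuses to average over them.

## Problem sizes used by the checks

The test suite trains toy configurations (one block per stage, width 8)
on tens of windows for its behavioural checks, and one full-size
`stage1_k5` run on the generator defaults (300 windows per class, 40
epochs at the standard schedule — so one learning-rate drop at epoch
30) for the held-out accuracy check. The acceptance script uses a
reduced 150 windows per class and 15 epochs. These sizes are the
package's own choice of a demonstration scale at which the synthetic
task is comfortably learnable while a complete run stays in the
minutes range on one CPU core.

## A worked example

```{r example, eval = FALSE}
library(nirsnet)

ws <- make_synthetic_dataset(n_per_class = 300, seed = 101)
sp <- split_windows(ws, split_spec(0.8, seed = 102))

fit <- nirsnet(sp$train, arch = "stage1_k5", channels = "O2Hb",
               train = train_config(epochs = 40), seed = 103)
evaluate_model(fit, sp$test)
plot(fit)                      # loss / accuracy curves with lr drops
summary(fit)                   # fit plus the full layer account
```

## Known limitations

* The engine is CPU-only and single-threaded; a full 120-epoch run on
  thousands of windows takes correspondingly long. The architecture,
  recipe and accounting are exact regardless.
* The synthetic task is far easier than real chest NIRS; reported
  synthetic accuracies are ceiling-level and say nothing quantitative
  about clinical performance.
* `ds`-variant halving uses decimation by default (`average` optional);
  the original description does not specify which.
* Model containers (`.rds`) embed the full architecture and training
  configuration, but no cross-framework checkpoint format is provided.
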