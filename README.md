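# nirsnet

Breathing-pattern classification from wearable NIRS haemodynamic signals
with a 1D pre-activation residual network.

A chest-worn near-infrared spectroscopy (NIRS) sensor records changes in
oxygenated (O2Hb) and deoxygenated (HHb) haemoglobin at 10 Hz. Respiration
imprints a quasi-periodic oscillation on these signals whose amplitude and
period differ between relaxed breathing, labored (loaded) breathing and
rapid/shallow breathing — the regimes a remote respiratory monitor needs
to tell apart. `nirsnet` classifies each 6.4-s window (64 samples) of such
a signal into one of the three conditions, end to end: no hand-crafted
features.

The model is a 113-weighted-layer 1D pre-activation ResNet built from
bottleneck residual units

    x_{l+1} = F(x_l, W_l) + x_l,

where `F` is three times (BN → ReLU → conv): a 1×1 narrowing, a 1×k
spatial and a 1×1 widening convolution. Its distinctive front component is
a size-reducing **Stage 1** — a stride-2 bottleneck unit with a 1×5 (or
1×3) spatial kernel — which halves the signal while forming wide-receptive
-field features, and outperforms plain decimation (the `ds` control
variant). Stages 2–4 stack 12 units each at widths
(16,16,64)/(32,32,128)/(64,64,256); global average pooling and a fully
connected layer produce the 3 class logits. Training is plain SGD:
momentum 0.9, batch 64, cross-entropy, learning rate 0.1 divided by 10
every 30 epochs, from scratch. Under the documented main-path accounting
convention the default network has 0.7 M parameters and needs 15 M FLOPs
per 64-sample forward pass.

The package also provides the surrounding protocol: CSV recording
ingestion with explicit artifact-exclusion masks, non-overlapping
windowing, stratified (per-class ceiling 80:20) and subject-level splits,
evaluation reports (accuracy, per-class recall, balanced accuracy,
confusion matrices, repeated-run mean/STD/best), and a synthetic
breathing-signal generator so the complete pipeline runs and is tested
without any recorded data. The numerical engine (im2col + BLAS
convolutions, batch norm, backprop, SGD) is implemented in the package and
verified against finite differences.

## Worked example

```r
library(nirsnet)

ws  <- make_synthetic_dataset(n_per_class = 300, seed = 101)
sp  <- split_windows(ws, split_spec(0.8, seed = 102))
fit <- nirsnet(sp$train, arch = "stage1_k5", channels = "O2Hb",
               train = train_config(epochs = 40), seed = 103)
evaluate_model(fit, sp$test)
```

```
Evaluation on 180 windows
  accuracy:          100.00%
  balanced accuracy: 100.00%
  per-class recall:
    baseline       1.00
    loaded         1.00
    rapid_shallow  1.00
  confusion (rows = true, cols = predicted):
               predicted
true            baseline loaded rapid_shallow
  baseline            60      0             0
  loaded               0     60             0
  rapid_shallow        0      0            60
```

Held-out windows of the synthetic task are classified essentially
perfectly — the generator's default conditions are well separated (a
simple periodogram-threshold baseline already exceeds 95%); the point of
the run is that the full 113-layer network, recipe and evaluation
machinery reproduce that separability end to end. On real recordings the
published task is much harder.

Architecture bookkeeping:

```r
print(layer_account(resnet_config("stage1_k5")))
```

```
Layer account (input length 64)
  weighted layers (conv + fc):  113
  parameters (main path):       717,523  (0.7 M)
  FLOPs (main path):            15,019,520  (15.0 M)
  + projection shortcuts:       42,240 params, 868,352 FLOPs
```

A thin command-line front-end covering the same pipeline
(`simulate`, `window`, `split`, `train`, `evaluate`, `inspect`) is
installed at `cli/nirsnet` inside the package directory; every
artifact-producing run writes a JSON manifest (config, seeds, input
digests, package version).

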