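Package: nirsnet
Title: 1D Pre-Activation Residual Networks for Breathing-Pattern
    Classification from Wearable NIRS Signals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Classifies simulated breathing conditions (baseline, loaded,
    rapid/shallow) from short windows of wearable near-infrared spectroscopy
    (NIRS) hemodynamic signals with a one-dimensional pre-activation residual
    network featuring a size-reducing bottleneck front stage. Provides CSV
    readers and fixed-length windowing for multichannel NIRS recordings,
    stratified and subject-level train/test splits, a from-scratch SGD
    training engine with the step learning-rate schedule, layer, parameter
    and FLOP accounting, evaluation reports (accuracy, per-class recall,
    balanced accuracy, confusion matrices), and a synthetic quasi-periodic
    breathing-signal generator so the full pipeline runs without any
    recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    graphics,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
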