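---
title: "Cross-subject transfer learning for P300 detection: models, choices, limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-subject transfer learning for P300 detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(p300tl)
```

## The problem

A P300 speller presents a 6x6 grid of symbols and flashes its 6 rows and 6
columns in random order; attending the intended symbol elicits a P300 — a
positive EEG deflection roughly 300 ms after the attended flash. Detecting
which row and which column carried the P300 identifies the symbol. The same
component supports target detection in rapid serial visual presentation
(RSVP), where images stream at ~5 Hz and roughly 1 in 10 is a target.

Single-trial P300 detection is subject-specific: amplitude, latency and
topography differ between people, so a classifier trained on one subject
transfers poorly to another. Collecting a large calibration set from every
new user is the main practical cost of these systems. `p300tl` implements a
transfer-learning pipeline that reduces that cost by combining four
ingredients:

1. **Deep feature extraction.** A compact CNN (batch norm, one
   channels-spanning convolution, batch norm, ReLU, two fully connected
   layers, softmax) is pre-trained on an existing *source* subject and
   fine-tuned on a small *target* calibration set with the feature layers
   frozen. The post-ReLU activations of the first fully connected layer are
   the deep features.
2. **Euclidean alignment (EA).** Each subject's feature set is mapped by
   the inverse square root of its mean outer-product matrix
   $\bar R = \frac1N \sum_n y_n y_n^\top$, i.e.
   $\tilde y_n = \bar R^{-1/2} y_n$, giving every subject an identity
   second moment and hence more comparable feature distributions. The
   reference can be computed offline (all trials at once) or online
   (running-mean update from one unlabeled trial at a time; after the last
   trial both coincide exactly).
3. **Source sample selection.** With the target reference
   $r = \frac1{N_T}\sum_j \tilde y_j^T$, every aligned source sample is
   ranked by its Euclidean distance to $r$ and only the $k$ closest are
   kept, discarding source trials least like the target data (negative
   transfer).
4. **Discriminative RBM.** A two-class restricted Boltzmann machine with
   $H = 10$ hidden units trained directly on the conditional
   $p(y \mid x) \propto \exp\!\big(b_y + \sum_j \mathrm{softplus}(c_j +
   U_{jy} + W_j x)\big)$, which is tractable — training uses the exact
   analytic gradient, no sampling.

Speller decoding sums the DRBM target probability per row/column code over
the first $N_r$ repetitions and takes the row and column argmax. Reported
metrics are the character-accuracy curve over $N_r$, the information
transfer rate $\mathrm{ITR} = 60\,\mathrm{bits}(P)/T$ with
$\mathrm{bits}(P)=\log_2 36 + P\log_2 P + (1-P)\log_2\frac{1-P}{35}$ and
$T = 2.5 + 0.175 \cdot 12 \cdot N_r$ seconds, and balanced classification
accuracy (BCA) for the imbalanced RSVP task.

## The synthetic session generator

No EEG recordings ship with the package; `simulate_speller_session()` and
`simulate_rsvp_session()` generate sessions that reproduce the two
paradigms' bookkeeping exactly (12 codes per repetition with one target row
and one target column; 5 Hz RSVP streams with a fixed target fraction) and
their signal structure approximately:

* **ERP model.** A Gaussian bump in time (default peak 300 ms, sd 60 ms,
  8 uV) with a smooth unimodal spatial profile peaking around 70% of the
  channel range, mimicking the centro-parietal P300 focus. Per-epoch
  latency jitter is Gaussian (default sd 20 ms), reflecting trial-to-trial
  latency variability.
* **Background noise.** Per-channel AR(1) with coefficient 0.95 plus white
  noise mixed 80/20 in power — a two-parameter stand-in for the 1/f-like
  EEG spectrum. The default scale (5 uV) was calibrated once so that
  within-subject single-trial detectability (CNN + DRBM test BCA around
  0.8) matches the range published for comparable RSVP systems; it was not
  tuned per experiment.
* **Cross-subject shift.** A random rotation of the channel space whose
  largest principal angle is `strength` (default 0.2 rad), a log-normal
  gain (sd 0.15) and a global latency offset (sd 10 ms). Real
  between-subject variability is moderate — electrodes sit at the same
  standard positions — which is why the rotation is kept small; an
  arbitrary orthogonal mixing would overstate the shift and make *any*
  cross-subject transfer useless.

What the generator deliberately does **not** model: eye-blink/EMG
artifacts, nonstationarity within a session, inter-channel noise
correlation, and volume-conduction head geometry. Consequently, passing
tests demonstrate correctness of the pipeline's mechanics and its behavior
under controlled distribution shift — not performance on real recordings.

## Numerical and design choices

* **Filtering** is cascaded Butterworth high-pass and low-pass (4th order
  each), applied forward-backward (`signal::filtfilt`), so the passband is
  flat within 5% and P300 latencies are not displaced by phase delay.
  Decimation applies an 8th-order Butterworth at 80% of the target Nyquist
  before keeping every q-th sample; event indices (0-based) are remapped by
  integer division.
* **Epoching** uses `T = round(duration * fs)` samples from a half-open
  `[0, duration)` window, reproducing both published input shapes
  (0.665 s x 240 Hz = 160 samples; 0.7 s x 64 Hz = 45 samples — rounding
  up from 44.8). No baseline correction and no artifact rejection are
  applied, and all channels are kept.
* **CNN.** Kernels span all channels; kernel height defaults to the
  stride (~T/10). The flattened convolution output feeds the first fully
  connected layer densely. During fine-tuning the frozen set is input batch
  norm + convolution + post-convolution batch norm: batch normalization is
  interleaved with the convolution and shares its feature-extraction role,
  and frozen batch-norm layers run on their stored statistics, which makes
  frozen parameters bit-identical by construction. Training is SGD
  (learning rate 0.01, momentum 0.9, weight decay 5e-4) with a 10%
  validation split, model selection on validation loss, and early stopping
  (default patience 10, at most 100 epochs; tests use smaller budgets).
  Class imbalance (1:5 speller, 1:9 RSVP) is not reweighted.
* **Alignment regularization.** $\bar R$ from ReLU features is often rank
  deficient; the inverse square root uses a scale-aware ridge
  `eps = 1e-6 * trace(R)/f` via symmetric eigendecomposition, which
  vanishes in the well-conditioned limit. The online mode recomputes the
  map after every trial (f <= 128, so the eigendecomposition is cheap) and
  uses no forgetting factor.
* **Selection.** Distances are Euclidean norms (the squared form ranks
  identically); ties break to the lower source index for determinism. The
  default `k` keeps half of the source samples; the speller study setting
  uses k = 7200.
* **DRBM.** Pure discriminative objective; the hybrid generative variant
  is exposed as `alpha` but not implemented (its gradient would require
  Monte Carlo sampling of the joint, a non-goal here). Optimization runs
  internally on z-scored features and returns exactly reparameterized
  raw-space parameters — `p(y|x)` is unchanged, but the fixed learning
  rate (0.05, 200 epochs) becomes insensitive to feature scale. This
  matters in practice: a fine-tuned CNN carries the source subject's
  batch-norm statistics, which can shrink target feature scale and would
  otherwise stall training at the majority-class solution.
* **Decoding.** Scores are summed probabilities (equivalently means)
  across repetitions — not per-repetition majority votes — with argmax
  ties resolved to the lowest code. The alphabet is A-Z then 0-9,
  row-major. Accuracies are reported as percentages rounded half-up to
  integers, and ITR uses N = 36 with the timing constants above.

## Validation scenarios and problem sizes

The test suite exercises every stage against independent oracles
(finite-difference gradients, exhaustive 2^H marginalization for the DRBM,
brute-force sorts for selection, closed forms for alignment) and then runs
the pipeline end to end at reduced scale, chosen to keep the full suite in
the minutes range on one CPU:

* **Paradigm bookkeeping** uses the full 85-character, 15-repetition
  session (15,300 epochs) at 8 channels — epoch counts are independent of
  the montage size.
* **Noise-free decodability**: 8 channels, 6 source / 3 calibration / 4
  test characters, zero noise and jitter, identity shift. The full
  pipeline must decode 100% of test characters at every repetition budget,
  offline and online.
* **Ablation ordering**: 8-channel speller pairs (10 source characters, a
  1-character target calibration, 12 test characters) at noise 10 uV —
  chosen so single-character accuracy sits mid-range rather than at
  ceiling, in the tiny-calibration regime that transfer learning exists
  for — with 15% of source epochs contaminated by 20 uV artifact-like
  low-frequency bursts, emulating the artifact-laden trials that make
  indiscriminate source pooling harmful. Across five seeded replicates,
  mean accuracy must be ordered: scratch CNN <= fine-tuned <= fine-tuned +
  EA <= fine-tuned + EA + selection.

## Known limitations

* Distance-to-mean selection is class-blind. On these synthetic features
  it removes large-amplitude outlier trials with perfect precision, but it
  cannot detect subject-level *similarity*: when the source pool mixes a
  subject similar to the target with a dissimilar one (different
  topography), the kept fraction from the similar subject is near chance.
  Benefits of selection should therefore be expected mainly when the
  source contains artifact-like outliers, which is also the regime the
  ablation scenario encodes.
* With a purely linear cross-subject shift (as generated here), EA removes
  the mismatch almost completely, so the margin left for selection is
  structurally small; real nonlinear shifts may leave more.
* The DRBM decision threshold is fixed at 0.5. Under strong class
  imbalance and weak features this collapses to the majority class; the
  speller decoder is unaffected (it compares summed scores across codes),
  but RSVP BCA with very small calibration sets degrades toward 0.5.
* Batch-norm running statistics make inference deterministic and
  batch-composition independent, but a fine-tuned model deliberately keeps
  the *source* statistics; targets whose scale differs wildly rely on the
  DRBM's scale-invariant training for robustness.

## A minimal run

```{r example, eval = FALSE}
tpl <- erp_template(n_channels = 8)
src <- simulate_speller_session(
  speller_config(6, n_channels = 8, subject_seed = 1), tpl,
  subject_shift(8, seed = 11), truth = c("H", "E", "L", "L", "O", "X"))
src_ep <- extract_epochs(bandpass_filter(src, 0.1, 30), c(0, 0.665))
# ... same for a target subject's calibration and test sessions, then:
# art <- run_training_stage(src_ep, tgt_train_ep, cnn_config(160, 8, 16, 16, 128))
# evaluate_speller(art, tgt_test_ep, truth)
```

The README shows a complete worked example with the numbers it prints.
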