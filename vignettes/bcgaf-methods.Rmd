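---
title: "Detecting atrial fibrillation in ballistocardiograms: models and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting atrial fibrillation in ballistocardiograms: models and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A ballistocardiogram (BCG) records the small mechanical recoil of the body
as the heart ejects blood, typically through a pressure-sensitive film under
a mattress. It needs no electrodes, which makes it attractive for screening
atrial fibrillation (AF) during sleep. AF shows up in the BCG in two ways:
the beat-to-beat (RR) intervals become "irregularly irregular", and the
mechanical beat complexes vary in amplitude and shape because ventricular
filling varies. `bcgaf` implements a detector that exploits both effects by
fusing features at two time scales:

* a **morphology feature**: a bidirectional LSTM reads one 1-s heartbeat
  segment (125 samples centred on the J-peak) and emits the last-step output
  of its second bidirectional layer, a 50-dimensional vector;
* a **rhythm feature**: each 24-s segment (3000 samples) is delay-embedded
  into three dimensions, `(x(t), x(t - tau), x(t - 2 tau))`, and projected
  onto the plane orthogonal to the diagonal `(1, 1, 1)`:

  $$u = \tfrac{1}{\sqrt 3}(x + y + z),\quad
    v = \tfrac{1}{\sqrt 6}(x + y - 2z),\quad
    w = \tfrac{1}{\sqrt 2}(x - y).$$

  The rotation is orthonormal, and any constant baseline shift moves points
  only along `u`, so the `(v, w)` portrait is baseline-invariant. A regular
  rhythm traces a tight repeating loop; an irregular rhythm smears it.

A convolutional network consumes the rhythm feature, its flatten output is
concatenated with the Bi-LSTM feature, an optional attention layer (SAM or
CBAM) re-weights the fused vector, and a dense + softmax head outputs the
AF/NAF decision.

## Embedding parameters

The delay is chosen as the first zero crossing of the unbiased normalised
autocorrelation; the dimension by the false-nearest-neighbours (FNN) rule
with the classical thresholds `rtol = 15`, `atol = 2` and acceptance when
the false fraction drops below 1%. On real mattress BCG these estimators
are reported to give `m = 3` and `tau = 40 ms` (5 samples at 125 Hz), and
the pipeline defaults to exactly that pair; estimation can be switched on
per segment with `embedding_params(x, tau = "auto", m = "auto")`.

Two estimator behaviours are worth knowing about:

* FNN is noise-sensitive: white in-band noise lifts the false-neighbour
  floor above 1% for any small `m`, so estimates on noisy segments saturate
  high. Estimator-agreement checks in the test suite therefore run on
  noise-free renderings ("clean" segments).
* AF segments are genuinely higher-dimensional than sinus segments: with
  serially uncorrelated RR intervals the quiescent state between beats
  cannot predict when the next complex arrives, which FNN correctly reports
  as persistent false neighbours. The global `(3, 5)` default is the
  sinus-rhythm estimate, applied to all segments exactly as a single global
  setting would be chosen in practice.

## The synthetic cohort

No public BCG/AF corpus matches this recording setup, so the package ships
a seeded generator used by every test and by the acceptance script.

* **Rhythm.** NAF intervals are `mean_rr + N(0, rr_sd)` plus a sinusoidal
  respiratory modulation; AF intervals are i.i.d. Gamma with mean `mean_rr`
  and coefficient of variation `rr_cv`. Defaults: `mean_rr = 0.7 s`,
  `rr_sd = 0.015 s`, respiratory modulation 1.5% at 0.25 Hz, `rr_cv = 0.25`.
  The AF law is an order of magnitude more variable than NAF, giving
  distributionally disjoint RR statistics - the contrast the detector is
  supposed to learn. The low NAF variability reflects the reduced
  short-term heart-rate variability of an elderly cardiac cohort asleep.
* **Morphology.** One heartbeat is five Gaussian bumps (H, I, J, K, L) with
  J strictly dominant. The default template is two-scale: a sharp I-J-K
  core (51 ms spacing, ~25-30 ms widths) over wide, low H and L waves that
  fill the diastolic interval. This shape was fixed once, by a design-time
  parameter study, so that the rendered records reproduce the embedding
  characteristics reported for real BCG: the autocorrelation of a clean
  sinus record first crosses zero at 5 samples and FNN settles at `m = 3`.
  A sparser template (isolated narrow complexes separated by a flat gap)
  fails both: the flat gap adds low-frequency autocorrelation mass that
  delays the zero crossing, and gap states are ambiguous to FNN.
  Per-subject morphology is drawn once per subject: amplitudes vary with
  sd 10% (truncated +/-30%), wave timings and widths with sd 3% (truncated
  +/-7.5%) - timing is kept tighter because it sets the dominant carrier
  frequency, which is far more stable across subjects than amplitude.
* **Rendering.** Beats are superposed at cumulative RR times, each scaled
  by `1 + N(0, amp_jitter_cv)` (5% for NAF, 20% for AF - AF pulse amplitude
  varies strongly with filling time), plus white noise (sd 0.05 of the J
  amplitude) and a 0.3 Hz baseline drift (amplitude 0.1) that the 0.7 Hz
  highpass must remove.

What the generator does **not** emulate: genuine hemodynamic waveform
changes within AF beats (only amplitude scaling), motion artifacts beyond
simple gain bursts, posture changes, and sensor nonlinearities. Passing
tests on this cohort demonstrate that the pipeline's mechanics are correct
and that it can learn the rhythm/morphology contrast; they do not certify
clinical performance on real recordings.

One consequence of the spec'd preprocessing worth flagging: because each
record is min-max normalised, the record maximum is set by its largest
beat. AF's amplitude variability makes that maximum large relative to the
typical beat, so AF's normalised phase-space loops are *smaller*: the
trajectory-dispersion statistic (mean distance to the `(v, w)` centroid)
separates the classes perfectly on synthetic data, but with AF below NAF.
The separation, not its sign, is what the pipeline relies on.

## Preprocessing

The chain is: zero-phase order-4 Butterworth bandpass 0.7-10 Hz (applied
forward and backward so J-peak latencies are not shifted); artifact masking
by a 2-s moving-RMS envelope (windows above 3x or below 0.2x the median
envelope are flagged and merged); per-record min-max normalisation to
[0, 1]; J-peak picking; then non-overlapping 24-s windows inside one label
interval and outside the mask, each paired with one 1-s segment centred on
the detected J-peak nearest the window centre that keeps a full margin
inside the window (62 samples before the peak, 62 after; the peak sits at
1-based index 63 - R indexes from 1, so this is "0-based index 62" in
zero-based notation).

The J-peak detector is deliberately simple - the J wave dominates by
construction and physiologically: local maxima of the normalised signal
within +/-0.15 s, a simplified prominence of at least 0.15 normalised units
above the higher of the two adjacent troughs (searched 0.3 s to each side),
and a 0.4 s refractory distance resolved in favour of larger peaks. All
thresholds are arguments.

## Networks and training

All layers, including backpropagation, are implemented in the package on
top of BLAS matrix products, and are verified in the test suite against
central-difference gradients (relative error below 1e-5) and straight-line
oracle evaluations of the attention formulas.

* **Bi-LSTM branch**: two bidirectional layers; 25 units per direction so
  the concatenated feature is the stated 50 wide (a bidirectional layer
  "with 50 hidden units" that feeds a 50-to-2 dense head can only mean 25
  per direction); dropout 0.5 between the layers; the second layer returns
  only its last step (forward direction at `t = T`, backward at `t = 1`).
* **CNN branch**: eight convolutions with channel progression
  32, 32, 64, 64, 128, 128, 256, 256 and four pools of size 3, one dropout
  (p = 0.25) after each pool. In the default *sequence* mode the rhythm
  feature is the L x 2 series of `(v, w)` and kernels are length-9,
  matching the 9 x 1 reading of the architecture table; 3000-sample
  segments give L = 2990 and a flatten width of 256 x 36 = 9216. In
  *image* mode the feature is an 81 x 81 raster, kernels are 9 x 9 (a 9 x 1
  kernel would never mix the second image axis) and pools are (3, 1), so
  the 81 rows collapse 81 - 27 - 9 - 3 - 1 and the flatten width is
  256 x 1 x 81 = 20736. The raster uses fixed bounds (the attainable range
  of `(v, w)` for unit-normalised signals) so pixel geometry is comparable
  across segments.
* **Fusion**: the two flatten outputs are concatenated (9216 + 50 = 9266 in
  sequence mode) and rectified before any attention layer - stochastic
  pooling is defined on non-negative activations and the Bi-LSTM feature is
  tanh-ranged, so the ReLU enforces the pooling contract at the fusion
  boundary.
* **SAM**: the fused vector is chunked into rows of length
  `T = ceiling(sqrt(L))` (zero-padded), shared `T x T` query/key/value maps
  with ReLU activations produce `Q'`, `K'`, `V'`, one softmax per row of
  `Q'K'^T / sqrt(d)` with `d = 100`, and the attended rows are flattened
  back and truncated to length L. The formulas are ambiguous about whether
  the chunks attend jointly or separately; stacking them as rows of one
  attention matrix realises the summation over chunks in a single
  well-defined operation and is the reading implemented here.
* **CBAM**: the fused vector is reshaped column-major to a 32 x L' map
  (zero-padded), because a "7 x 7" spatial filter cannot act on a flat
  vector; the 1-D realisation uses a length-7 filter. Channel gating pools
  each channel by average, max and stochastic pooling, passes the three
  vectors through a shared 32 - 4 - 32 bottleneck MLP (reduction 8), sums
  and applies a sigmoid; spatial gating pools across channels into a 3 x L'
  spliced map, convolves with the length-7 filter and applies a sigmoid.
  The spatial product is taken with the channel-gated map (standard CBAM
  ordering); stochastic pooling samples proportionally to activation in
  training and returns the magnitude-weighted expectation in evaluation,
  so evaluation is deterministic.
* **Training**: Adam (lr 5e-4, the study's setting), cross-entropy, batch
  size 32 by default, 30 epochs by default. Two initialisation choices aid
  early optimisation without touching the architecture: classifier heads
  start at zero (initial logits are uninformative rather than confidently
  wrong), and CBAM's expansion MLP layer and spatial filter start at zero
  so both gates open at 0.5 and the attention layer is feature-preserving
  (up to a constant) until it has learnt a re-weighting. One integer seed
  drives
  initialisation, shuffling, dropout and stochastic pooling through a
  splittable label-hashed seed derivation, so identical configuration and
  seed reproduce byte-identical results single-threaded. Training and
  validation sets must be subject-disjoint; the best-validation weights are
  returned.

## Evaluation protocol

AF is the positive class. Accuracy, sensitivity, precision and specificity
are exact fractions internally; display rounding is half-up to three
decimals (`round_half_up()`), the convention of the published tables. The
package ships a transcription of the published confusion matrices and
metric tables and `reproduce_paper_tables()` recomputes all 64 cells: 61
match exactly, two accuracy cells (computing to 0.9295 and 0.8895) were
printed truncated rather than rounded and are flagged as documented
truncation discrepancies, and one precision cell (the DBN baseline) is
printed one unit of the third decimal above the value its own confusion
matrix yields (710/976 = 0.7275, so 0.727 under any rounding, printed
0.728) - an internal inconsistency of the printed source that the report
flags as a mismatch.

Splits are always at subject level: an 80/20 holdout whose training side is
divided 4:1 into training and validation, and tenfold subject-level
cross-validation with pooled test predictions (the format of the published
2000-segment tables). Fold assignment is seeded and invariant to subject
input order.

## Problem sizes used by the automated checks

The test suite and the acceptance script scale the study down so the whole
chain runs comfortably on one CPU: the held-out-accuracy check trains the
fused CBAM model on a 10-subject, 400-pair cohort for 5 epochs at batch 16;
the configuration-ordering check (fused CBAM vs rhythm branch alone) uses
ten paired repetitions on 4-subject, 48-pair cohorts, both models trained
6 epochs at batch 4 and learning rate 1e-3 with regularisation off
(dropout noise prevents any learning at that sample size and would make
the comparison vacuous); the estimator-agreement check uses 15 clean
sinus records; dispersion
separation uses a 10-subject, 400-segment cohort. These sizes are the
package's chosen demonstration scale, small enough to iterate on and large
enough that the learning signal is unambiguous.

## Known limitations

* The generator's AF morphology is amplitude-only; real AF also changes
  complex shape beat to beat.
* The FNN estimator inherits the classical thresholds; on noisy segments
  it reports high dimensions rather than denoising first.
* Image-mode training works but is considerably slower than sequence mode
  (2-D convolutions dominate); sequence mode is the default and the mode
  exercised end-to-end by the automated checks.
* The networks run on BLAS threads only; there is no GPU path.
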