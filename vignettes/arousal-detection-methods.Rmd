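---
title: "Detecting cortical arousals in polysomnography: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting cortical arousals in polysomnography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(arousalNet)
```

## Scope and data model

arousalNet detects cortical arousals — abrupt EEG frequency shifts of
3–15 s with at least 10 s of preceding sleep, with a simultaneous chin-EMG
increase required in stage R — from three PSG channels (EEG, EOG, chin
EMG), and evaluates detections the way a sleep laboratory consumes them:
as discrete events and as the arousal index (ArI, events per hour of
sleep). Time is measured in seconds from record start; all event
intervals are half-open `[onset, onset + duration)`; hypnogram epoch *i*
covers `[30(i-1), 30i)`. Total sleep time is 30 s times the number of
non-wake epochs, the standard scoring convention.

Records enter an analysis set only if they last at least 5 h and every
EEG channel is sampled at 200 Hz or more (the rate recommended for
arousal scoring); both cutoffs are arguments of `eligibleRecord()`.

Signals travel as EDF, the de-facto PSG interchange format (the reader
and writer cover continuous 16-bit EDF, which is what the rest of the
pipeline needs; a write/read round-trip is exact up to the 16-bit
quantization step). Annotations use a plain TSV dialect
(`onset_s`, `duration_s`, `label`) because scoring-software export
formats are proprietary and vary by vendor; hypnograms are one stage
symbol per line.

## Preprocessing

Each selected channel is antialiased and resampled to 50 Hz, then
normalized:

* **FIR design.** The low-pass is a Hamming-windowed sinc with cutoff at
  the output Nyquist (25 Hz) and enough taps that the transition band
  ends by 1.2 × cutoff, where folded aliases would land in the output
  band. It is applied forward–backward (zero phase), which preserves
  event timing — essential because detections are later matched to
  annotations by temporal overlap — and squares the stopband
  attenuation. Record edges are padded by anti-symmetric reflection,
  which keeps value and slope continuous and keeps filter onset
  transients to roughly −40 dB even within a second of the record edge.
  Resampling to arbitrary rational ratios goes through linear
  interpolation of the filtered signal; for integer ratios this reduces
  to exact decimation. DC is preserved exactly (unit-sum taps).
* **Moving normalization.** The moving mean over a centered 18-min
  window is removed and the residual is divided by its moving RMS over
  the same window (edge-truncated; RMS floored at 1e−8 so flat segments
  map to zero). The 18-min scale is long against any arousal but short
  against drifts in electrode impedance, so event morphology survives
  while gain and offset differences do not. Whether the RMS should be
  taken of the raw or the mean-removed window is not determined by the
  method's description; the mean-removed form (a local z-score) was
  chosen as the standard standardization contract.
* **Labels.** Annotated arousals are extended −2 s/+10 s (autonomic
  responses precede and outlast the cortical shift), clipped to the
  record, merged where extensions overlap (a binary track cannot encode
  overlap), and rasterized at 50 Hz with the half-open sample-time rule
  `y[t] = 1 ⇔ t/fs ∈ event`. A 3-s arousal therefore contributes a 15-s
  positive run, which is also why the event post-processing uses a 15-s
  minimum length.

## The U-net

`buildUNet()` constructs a fully convolutional 1D U-net: `depth` encoder
double-convolution blocks each followed by ×`poolFactor` max-pooling,
and `depth` symmetric decoder blocks each preceded by nearest-neighbour
upsampling and concatenation with the matching encoder skip; a final 1×1
convolution and sigmoid yield a 50 Hz probability track of exactly the
input length (all convolutions are same-padded). The default spec —
depth 4, i.e. eight double-convolution blocks, kernel 21, base 16
filters doubling per level and capped at 256 — follows the published
architecture family; where the source figure's per-block filter counts
are not legible in text form, standard U-net doubling was adopted and
left configurable. "Eight layers of double convolution" was read as a
symmetric 4+4 encoder/decoder split with the bottleneck folded into the
deepest level; the pooling factor (4) is likewise a design choice, giving
×256 temporal downsampling so the deepest kernels see ±85 s of context —
enough to learn that labels extend 10 s past the visible burst.

Forward and backward passes are implemented directly on BLAS matrix
operations (im2col convolutions); the backward pass is verified against
finite-difference gradients in the test suite. Inference runs in
fixed-length chunks (default 4096 samples ≈ 82 s) with 50% overlap,
stitching the central half of each chunk so interior samples are always
predicted with symmetric context; record edges keep the full chunk.
Chunk lengths are rounded up to a multiple of `poolFactor^depth`.

## Training

`trainModel()` optimizes binary cross-entropy with Adam. The learning
rate follows a triangular cycle between 0.003 and 0.00075 with a
four-epoch half-period (the published bounds and period; the triangular
shape is the convention of the cyclical-LR literature the bounds come
from). An LR range test (`lrRangeTest()`) is available to re-derive
bounds on new data: it brackets the contiguous region of candidate rates
that improve the loss and contain the steepest descent.

Augmentation draws one channel per role (`selectChannels()`) and scales
each channel by an independent factor uniform in [0.8, 1.3]. The
published description ("random noise with a factor") does not fix the
injection semantics; multiplicative per-channel scaling was chosen as
the reading that makes the factor dimensionless, and it composes with
the moving normalization to emulate gain variability. Batches are random
fixed-length chunks (default 2048 samples ≈ 41 s); arousal labels are
rare, so half the chunks are steered to contain at least one positive
sample. Validation sample AUPRC at 50 Hz decides the retained
checkpoint, and training stops after 15 epochs without improvement.
Splits are participant-wise (`makeSplit()`, 80/20 train/validation of
non-test participants), asserted so no participant leaks across splits.

## From probabilities to events, and evaluation

The probability track is averaged to 1-s segments, binarized at a
threshold chosen on the validation set by micro event F1 (ties break
toward the lower threshold), positive runs separated by gaps ≤ 3 s are
merged, and events shorter than 15 s are dropped. The gap comparison is
inclusive (`≤ patience`), a choice the method description leaves open.
The 15-s minimum is deliberately consistent with the −2/+10 s label
extension; the AASM's own 3-s floor is kept as a separate knob
(`aasmMinLength`) for pipelines that skip label extension. Whether
predicted events during scored wake should be removed before computing
the ArI is not specified in the method; the package computes the ArI
from all detected events by default.

Event matching counts any temporal overlap, with the two asymmetric
double-coverage rules: two predictions over one reference give 1 TP +
1 FN, two references under one prediction give 2 TP + 1 FP. Only the
two-fold cases are defined by the source method; the package extrapolates
to k-fold coverage (k predictions over one reference: 1 TP + (k−1) FN;
k references under one prediction: k TP + (k−1) FP) and documents this
as an extrapolation. Micro F1 pools confusion counts over records before
the ratio. A degenerate ArI Pearson correlation (zero variance) is
reported as missing rather than 1.

The bias analysis groups per-record ArI errors by metadata (diagnosis
groups against the exclusive normal-findings reference; decade age bins
18–29 … 80+, boundaries configurable since the source figures do not
print them; sex) and runs Shapiro–Wilk per group, Kruskal–Wallis,
Dunn's post-hoc z-tests with Bonferroni correction (implemented with the
standard tie correction, as no Dunn implementation ships with the
environment's R packages), and pooled-sd Cohen's d with the
0.2/0.5/0.8 magnitude bins. Group significance flags come from the
Dunn–Bonferroni p against the reference, matching the described test
chain.

## The synthetic generator

`simulateRecording()` emulates the *statistical structure* the detector
exploits, not physiology: stage-dependent AR(1) background noise (deeper
NREM = slower, larger), arousals as additive 12–20 Hz bursts with 0.5-s
cosine ramps at `burstGain` × the local background amplitude (default 3,
chosen so a compact model learns the task in minutes on one CPU), chin
EMG amplified by `emgBurstGain` during stage-R arousals, a semi-Markov
hypnogram, and arousal placement as a renewal process on sleep time
calibrated to the target ArI (defaults 25/h, the clinical-cohort
average) under the 10-s minimum-gap and 3–15 s duration constraints.
Over 8-h records the realized ArI tracks the target within ±2/h; short
records undercount slightly because sleep bouts truncate the renewal
process. Metadata (age ≈ N(57.8, 15.8) clipped to 18–92, 40% female,
non-exclusive diagnosis marginals of a clinical cohort) feed the bias
machinery. `simulateCohort()` additionally emulates an imperfect scorer
by perturbing the truth annotations to a controlled ArI error
(half-normal baseline plus optional per-group shifts), which gives the
bias analysis a fully synthetic end-to-end path.

What passing tests on this generator do **not** show: robustness to real
EEG nonstationarity, artifacts, montage drift, scorer disagreement, or
arousal morphologies beyond an additive band-limited burst. The
generator is a correctness and calibration instrument, not a claim about
clinical performance.

## Numerical and scale choices

Problem sizes in the tests and the acceptance script are desk-scale by
design: 10-min records, cohorts of tens of records, a depth-4/8-filter
U-net (~134k parameters), six training epochs. The same code paths run
unchanged at overnight scale; only the configuration grows. Probability
clamping for the cross-entropy is at 1e−7; Adam uses the conventional
(0.9, 0.999, 1e−8) moments; weight initialization is He-scaled Gaussian,
reproducible given a seed. Training histories are bit-reproducible for a
fixed seed with augmentation disabled (single-threaded BLAS assumed; a
multi-threaded BLAS may reorder floating-point reductions).

## Known limitations

* Only the 50 Hz preprocessing chain is implemented as the default; the
  alternative 128/200 Hz variants the source work rejected are out of
  scope (rates are configurable arguments throughout).
* The k-fold overlap accounting beyond the printed two-fold cases is an
  extrapolation, flagged above.
* The EDF layer targets continuous 16-bit EDF as produced by the
  package itself and standard recorders; EDF+ discontinuous records and
  embedded annotation streams are not parsed.
* Training is CPU-bound pure R; it is sized for method validation, not
  for fitting thousands of overnight records.
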