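---
title: "Detecting 3 Hz spike-wave discharges: models, simulator and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting 3 Hz spike-wave discharges: models, simulator and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Typical absence seizures appear in scalp EEG as generalized, roughly 3 Hz
spike-and-slow-wave discharges (SWDs), largest over frontal and central
electrodes, against an ongoing background of low-amplitude, noisy,
low-frequency activity contaminated by blink, eye-movement, EMG and ECG
artifacts. In long-term recordings the seizures occupy on the order of 1%
of the record, so the detection problem is a severely imbalanced sequence-
labeling task: given multichannel EEG, return the time intervals of the
discharges.

`swdnet` implements a complete detection pipeline for this task —
preprocessing, a residual CNN + bidirectional GRU sequence labeler (with
three simpler comparison architectures), focal-loss training, and
event-based scoring — together with a seeded synthetic-EEG simulator so
that every stage is exercised end to end without clinical data.

## Pipeline overview

1. **Input.** EDF/EDF+ recordings; seizure annotations from an EDF+
   annotation channel or a sidecar CSV (`start_s,end_s,label`). The 19
   canonical 10–20 channels (`fp1 … pz`) are selected after label
   normalization (case, `"EEG "` prefixes, reference suffixes, and the
   modern T7/T8/P7/P8 aliases of the legacy T3/T4/T5/T6 names). Times are
   seconds from record start, half-open intervals.
2. **Resampling.** All records are brought to a 100 Hz working rate by
   Fourier-domain resampling (spectrum truncation), which is inherently
   anti-aliased and preserves in-band amplitude to well under 1%.
3. **Filtering.** An order-12 Butterworth band-pass with half-power edges
   at 0.16 Hz and 35 Hz removes drift, EMG-band energy and 50 Hz mains
   interference. "Order 12" is the total band-pass order: a 6-pole
   low-pass prototype, transformed, yielding 6 biquad sections. The filter
   is realized in cascaded second-order sections because an order-12
   band-pass in direct `(b, a)` form is numerically unstable (section pole
   moduli reach 0.9995). It is applied zero-phase (forward–backward) by
   default so event boundaries are not delayed; this also squares the
   magnitude response, taking the single-pass ~19 dB at 50 Hz (at 500 Hz
   sampling) to ~39 dB.
4. **Features.** A short-time Fourier transform with a Hann window of 256
   samples (2.56 s at 100 Hz) and 50% overlap produces a spectrogram;
   each frame contributes 128 log-magnitude bins (`log(1+|X|)`, bins
   0–127, i.e. 0–50 Hz) concatenated with 128 raw samples (the same
   window decimated by 2), giving 256 features per frame per channel.
   Both halves use the identical window and hop. Per record, the raw
   halves are z-scored per channel and the spectrogram halves are scaled
   by one global standard deviation, removing inter-device amplitude
   scale.
5. **Examples.** Consecutive non-overlapping blocks of 64 frames form the
   network input unit, a 64 × 256 × 19 tensor; a frame is labeled
   positive when at least half of its 2.56 s window lies inside a seizure
   event. The trailing partial block is zero-padded with masked labels;
   masked frames never contribute to the loss or to metrics.
6. **Network.** See below; output is one probability per frame.
7. **Decoding.** Frames at or above threshold 0.5 are grouped into runs;
   runs closer than 1 s are merged and events shorter than 1 s dropped.
8. **Scoring.** Predicted events match true events one-to-one, greedily
   in time order, when their overlap exceeds 2 s. TPR, TNR, PPV, NPV and
   F1 are computed from the resulting counts; true negatives are defined
   by tiling seizure-free background into 10 s windows and counting those
   untouched by any prediction (events carry no natural negative count,
   so a discretization is unavoidable; the window length is echoed in
   every report).

## The architectures

The flagship `resnet_bigru` model is a four-block residual CNN encoder
followed by a bidirectional GRU sequence head. Its construction is
asserted, layer by layer, against fixed reference parameter counts; a
mismatch is a build error, not a warning.

**Encoder.** Channel plan 19 → 32 → 64 → 128 → 64. Each block is
`conv 3×3 – batch norm – ReLU – conv 3×3 – batch norm` on the main path,
a biased 1×1 projection on the identity path, elementwise Add + ReLU,
then max pooling with kernel and stride (1, 2): pooling halves only the
feature axis, so the 64-frame sequence axis survives the whole network
(64 × 256 → … → 64 × 16 with 64 channels). The 3×3 convolutions are
bias-free — the batch norm that follows each one absorbs any bias — while
the 1×1 projections carry a bias; this convention is forced by the
reference counts (e.g. the 1×1 19→32 projection has 19·32+32 = 640
parameters, and conv 3×3 19→32 has 9·19·32 = 5472).

**Head.** The encoder output (64, 16, 64) is flattened per frame to
64 × 1024 and passed through two sequence-returning bidirectional GRU
layers (128 units per direction, tanh), then per-frame dense layers
256 → 128 (ReLU) → 1 (sigmoid). The GRUs use the dual-bias
("reset-after") gate formulation — the reset gate multiplies the
recurrent product after its own bias is added, so each gate carries two
bias vectors and a direction counts `3·u·(f + u + 2)` parameters; with
f = 1024 and u = 128 the bidirectional pair counts exactly 886,272. The
single-bias formulation cannot reproduce that count, which is why the
dual-bias variant is the one implemented.

The published description of the head contains a handful of rows whose
printed numbers are mutually inconsistent (an input width of 164 where
the encoder emits 64; a 1280-wide bidirectional output where 128 units
per direction give 256; several dense counts implying different widths
than their neighbors). Those rows are not asserted; the package's own
arithmetic-consistent choices are: second bidirectional layer 128
units/direction (296,448 parameters), dense 256→128 (32,896), dense
128→1 (129). A sigmoid output is the shipped default so the head emits
probabilities; a ReLU output is available behind a flag for completeness.

**Comparison variants.** `cnn_only` removes the projections, Adds and
recurrence (conv stack + per-frame dense head); `gru_only` flattens the
raw 256 × 19 frame features straight into the bidirectional head;
`cnn_gru` is the shortcut-free conv stack with the recurrent head. All
four accept 64 × 256 × 19 and emit 64 per-frame probabilities.

**Implementation.** No deep-learning framework is involved: the layers,
backpropagation, and optimizer are implemented in the package, with the
convolutions (im2col + BLAS GEMM) and the per-channel batch-norm passes
in compiled code and everything else in R. Every operation's gradient is
verified against central finite differences in the test suite at small
tensor shapes (the operations are shape-generic; only the builders pin
the canonical input). Batch-norm running statistics are bias-corrected
exponential averages (momentum 0.9), so inference is usable after few
updates.

## Training

The loss is focal binary cross-entropy: label 1 contributes
`-alpha (1-p)^gamma log p`, label 0 `-(1-alpha) p^gamma log(1-p)`, with
alpha = 0.25 and gamma = 2 by default — the standard remedy for the
positive-class scarcity of long-term EEG; with gamma = 0 and alpha = 0.5
it reduces to half the ordinary cross-entropy (a test asserts this).
Optimization is Adam (the "adaptive learning rate" component) at 1e-3
with L2 (1e-4) on convolution and dense kernels only — biases,
batch-norm and recurrent weights are unpenalized — and dropout 0.3 after
each recurrent layer and the first dense layer, active only during
training. Checkpointing keeps the epoch with the best validation
frame-F1; an optional early stop ends training once a target validation
F1 is reached. All randomness (shuffling, dropout, initialization)
derives from the configured seed, and two runs with the same seed and
data are bit-identical under single-threaded BLAS.

## The synthetic-EEG simulator

The simulator generates what the detector is meant to find, with the
statistical structure of the clinical description rather than a
biophysical model:

* **Background:** per-channel 1/f ("pink") noise at 15 µV standard
  deviation plus an amplitude-modulated 9 Hz alpha rhythm, larger on the
  posterior channels (8 µV vs 2 µV elsewhere) — zero-mean, 10–50 µV
  amplitudes, monotonically decreasing octave-band spectrum.
* **Discharges:** spike-wave complexes repeating at 3 Hz — a sharp
  positive Gaussian spike (~70 ms, 120 µV) followed by a slow half-sine
  (~260 ms, 80 µV) — synchronous across channels, scaled ×1.5 on
  fp1/fp2/f3/f4/fz/cz, edge-tapered over half a complex. The published
  phenomenology gives no waveform equation; this shape is the package's
  choice and produces the right spectral signature (a dominant 2.5–3.5 Hz
  peak ≥ 6 dB above background).
* **Artifacts:** frontal-dominant biphasic blinks (~0.3 s, ~100 µV),
  broadband 25–45 Hz EMG bursts on temporal channels, and a faint
  continuous ECG spike train; all injected intervals are logged for test
  introspection.
* **Imbalance:** event durations are drawn uniformly from 4–15 s until
  their total reaches the target seizure fraction (default 0.0108, the
  clinical corpus statistic; the construction guarantees the total stays
  within ±20% of target), and placed uniformly at random with ≥ 5 s
  separation. A `balanced` preset (fraction 0.2) exists for fast CPU
  training exercises.
* **Determinism:** one seed drives everything; corpus records derive
  per-record seeds from it.

Records default to 500 Hz so the resampling path is always exercised.

What the simulator does **not** reproduce: patient-to-patient waveform
variability, atypical/myoclonic/eyelid variants, electrode artifacts
(pops, detachment), state changes (sleep), or any channel covariance
structure beyond the frontal/posterior gain maps. Passing the end-to-end
tests therefore demonstrates that the pipeline is implemented correctly
and can learn the target pattern — not that clinical accuracy figures
transfer.

## Numerical choices and degenerate inputs

* STFT frames use the absolute sample index in the complex exponent (the
  windowed-segment DFT times a per-frame phase factor), the discrete
  realization of the integral definition; magnitudes — all that the
  features consume — are unaffected. A brute-force direct-sum DFT oracle
  pins the implementation to < 1e-9 relative error.
* The Hann taper is the default; the window function in the published
  formula is generic.
* The feature split 128 + 128 = 256 is a design decision: a one-sided
  256-point spectrum alone has 129 bins, so "spectrogram concatenated
  with raw" cannot fill a 256-vector without an explicit split. The
  printed window-length-to-seconds table is internally inconsistent
  (64 samples at 100 Hz is 0.64 s, not 0.75 s); sample counts are
  authoritative throughout.
* The low cutoff of 0.16 Hz is taken literally, in Hz.
* Constant (degenerate) channels normalize to zeros, with a logged
  message; probabilities are clipped to [1e-7, 1 − 1e-7] inside the loss;
  zero metric denominators yield flagged `NA`s, never errors.
* Max-pool ties break toward the earlier feature index. Event lists merge
  touching same-label intervals on construction, making them
  order-independent.
* Duplicate canonical channels are an error rather than first-wins, so a
  montage mistake cannot pass silently.

## Problem sizes in the shipped tests

The end-to-end check trains the full model on 20 simulated records of
120 s each (balanced preset, 15/5 record train/validation split, ≤ 15
epochs with early stop at validation F1 0.98, batch 8) — chosen as the
smallest corpus on which the learnability claim is meaningful — and then
detects events across all 20 records with the 2 s overlap rule.
Optimizer smoke tests use the `gru_only` variant, the cheapest
architecture that still exercises the full loss/optimizer/checkpoint
path. The simulator statistics check uses a single 3600 s record at the
clinical imbalance (0.0108), generated at 250 Hz.

## Known limitations

* CPU-only, double precision; no GPU path and no architecture search.
* The EDF writer emits 16-bit standard EDF with one-second records
  (zero-padding the tail) and supports a single common sampling rate
  across signals.
* Greedy in-time event matching is one-to-one; a single prediction
  spanning two seizures counts one TP and one FN, a deliberate, echoed
  choice.
* Event-level true negatives require a tiling discretization; reports
  echo the window length so the convention is always visible.
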