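---
title: "Heart-sound segmentation and CHD classification: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Heart-sound segmentation and CHD classification: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcgseg)
```

# The problem

A phonocardiogram (PCG) records the heart's acoustic activity. Each cardiac
cycle passes through four states — the first heart sound (S1), systole, the
second heart sound (S2), diastole — and pediatric congenital heart disease
leaves auscultatory signatures on them: an atrial septal defect (ASD) tends
to accentuate or split S2 and is often accompanied by a tricuspid
regurgitation murmur; a ventricular septal defect (VSD) produces a harsh
holosystolic murmur. `pcgseg` implements a two-stage pipeline: (1) a neural
frame-wise segmenter that labels every 20 ms frame with one of the four
states, and (2) a fragment-level classifier (normal / ASD / VSD) operating
on slices spanning an integer number of cardiac cycles, with an experiment
sweeping that cycle count.

# Pre-processing

All audio is band-passed with a second-order Butterworth filter (25–400 Hz),
resampled to 2 kHz, and peak-normalized. Two choices deserve comment:

* **Zero-phase filtering.** The filter is applied forward and backward
  (`signal::filtfilt`), doubling the effective order but removing group
  delay. Segmentation is scored with ±80–100 ms tolerance windows, so a
  filter-induced timing shift would directly bias the evaluation; we trade
  a steeper effective roll-off for exact timing neutrality.
* **Filter-then-resample order** (configurable). Filtering at the native
  rate keeps the design band well inside Nyquist for any input rate.

The chain is idempotent only approximately: a second pass attenuates
transition-band content again (about 0.5 % at 80 Hz for the order-2 design),
so the fixed point is reached to roughly 1 %, not machine precision. The
tests assert exactly that.

# Envelope features

Four envelopes, each resampled to a common 50 frames/s grid (20 ms frames;
the 80–100 ms tolerance windows span 4–5 frames) and standardized per
channel over the record:

1. **Hilbert envelope** — magnitude of the analytic signal. A `"literal"`
   mode returning `|H{x}|` (the bare Hilbert transform's absolute value) is
   provided because the phrase is ambiguous; the analytic magnitude is the
   default since it is the standard amplitude envelope.
2. **Homomorphic envelope** — `exp(LPF(log |analytic| + eps))` with a
   first-order zero-phase Butterworth low-pass at 8 Hz. The cutoff is a
   package choice: slow enough to smooth intra-sound oscillation, fast
   enough to keep S1 and S2 as separate humps. All-zero input returns the
   `eps` floor directly (the low-pass transient would otherwise amplify the
   floor unpredictably).
3. **Wavelet envelope** — absolute value of the Daubechies-6 level-3 detail
   band (125–250 Hz at 2 kHz). The DWT is periodized and hand-implemented
   (no wavelet package is available as a dependency); its filters and index
   conventions are pinned by a frozen reference fixture in the tests. By
   default the detail band is reconstructed back to signal length so all
   channels share one time axis; raw decimated coefficients (length ≈ N/8)
   are available via `mode = "coefficients"`.
4. **PSD envelope** — mean power spectral density over a band, computed on
   0.05 s Hamming windows with 50 % overlap. The band default (40–60 Hz) is
   a package choice targeting the dominant S1/S2 energy; it is configurable.

# The TBLSTM segmenter

The segmenter stacks:

1. **A multi-scale temporal convolutional network.** Five residual blocks
   with dilation rates 2, 4, 8, 16, 16. Each block is a dilated causal
   convolution followed by a plain causal convolution, one ReLU after each,
   plus an identity skip (1×1 projection where channel counts change).
   Causal convolutions use left zero-padding of `(K−1)·d`, so the output at
   frame *t* never sees frames after *t* (receptive field `(K−1)·d+1`, both
   verified by perturbation tests). Between blocks the sequence is
   max-pooled (window 2, stride 2), forming a serial pyramid; each block's
   pre-pool output is linearly interpolated back to the input frame count
   and the five maps are concatenated channel-wise. Concatenation (rather
   than summation, which is also implemented) preserves per-scale
   information; the upsampling rates are implied by the pooled lengths.
2. **A bidirectional LSTM** (64 units per direction by default) over the
   fused features, capturing rhythm context in both directions; a
   unidirectional variant is available.
3. **Dropout** (0.25) after the Bi-LSTM, active only during training.
4. **A dense + softmax frame classifier** over the four states.

Kernel size (3), block width (32), LSTM width (64) and the dropout rate are
package choices where the architecture description leaves them open.

Training minimizes per-frame cross-entropy with Adam (learning rate 0.001,
batch size 32, 90 epochs by default). The forward pass *and* the
backpropagation are hand-authored in vectorized base R — minibatches are
(time × batch × channel) arrays, records are grouped by frame count, and
every layer has an analytically derived backward pass validated by
finite-difference checks during development. All randomness (initialization,
shuffling, dropout) flows through one seed; two runs with the same seed are
bit-identical. Weight initialization is uniform fan-in scaled, with the LSTM
forget-gate bias started at 1 (standard practice, helps early gradient
flow). Inverse-frequency class weights are available but off by default:
diastole dominates the frame counts, yet the unweighted loss already
recovers the minority states well on the synthetic data.

# Decoding and fragmentation

Posteriors are decoded by argmax, then runs shorter than a per-state minimum
duration (S1 60 ms, systole 80 ms, S2 50 ms, diastole 120 ms — derived from
the physiological durations implied by the tolerance windows) are absorbed
into the longer neighbour until a fixed point; an optional projection
enforces the cyclic order S1 → systole → S2 → diastole. A cardiac cycle runs
from one S1 onset to the next; leading/trailing partial cycles are dropped.
Fragments of `n` cycles slide one cycle at a time (stride 1, maximal
overlap), so consecutive fragments share `n−1` cycles and every cycle is
covered.

# Tolerance-window evaluation

Scoring is frame-level one-vs-rest per state with event-level tolerance for
S1 (100 ms) and S2 (80 ms): predicted and true intervals of the state are
matched one-to-one greedily in order of increasing onset distance, accepting
matches within the tolerance; frames of matched pairs count as true
positives, unmatched predicted intervals as false positives, unmatched true
intervals as false negatives. Matching by increasing distance makes the
matched set — hence sensitivity — provably monotone in the window width,
which the tests assert. Systole and diastole are scored without tolerance.
Where true negatives are needed, the one-vs-rest framing defines them (a
4-state problem has no canonical frame-level TN).

Metrics are Acc, Se, P, F1 per state with unweighted (macro) averaging. The
precision formula as printed in some of the heart-sound literature reads `P = TN/(TN+FP)` — specificity under
standard nomenclature. Both are implemented: `precision_mode = "printed"`
preserves the literal formula; the default `"conventional"` uses
`P = TP/(TP+FP)`, matching how F1 is normally formed. Across records, counts
are pooled first, then metrics computed (micro across records, macro across
states).

# MFCC features and classification

Fragments are framed at 20 ms / 10 ms hop with Hamming windows; each frame
passes through a zero-padded 256-point FFT, a 26-filter triangular mel bank
over 30–500 Hz, a log (floored at `eps` for silent frames), and an
orthonormal DCT-II keeping c0–c12 (order 12 plus energy; `drop_c0`
available). First- and second-order regression deltas (±2 frames,
edge-replicated) complete the 39 dimensions per frame.

The FFT size is a deliberate deviation from "next power of two above the
frame length" (64 at 2 kHz): with 31 Hz bins, several of the 26 mel filters
between 30 and 500 Hz would have empty support, producing constant log-floor
channels. Zero-padding to 256 gives 7.8 Hz bins and every filter positive
mass; zero-padding changes spectral interpolation, not resolution, so the
features remain comparable.

Variable-length fragments become fixed 78-dimension vectors by per-dimension
mean and standard deviation over frames — the simplest aggregator that keeps
both level and variability information; it is the main invented bridge
between frame features and the fragment-level classifier. PCA (fitted on
training rows only, retaining 95 % variance) and z-scoring with training
statistics precede a 100-tree random forest (`randomForest`, remaining
hyperparameters at library defaults). The cycle-count sweep re-cuts
fragments, re-extracts features, and refits PCA + forest per fold for each
cycle count 1–9. Folds are split at the *recording* level, stratified by
class: overlapping fragments of one recording share most of their samples,
and letting them straddle a train/test split would leak. This is possibly
stricter than the original protocol and is the most likely source of
divergence from protocols that split at the fragment level; PCA is likewise fitted per fold
(leakage-safe), another possible divergence.

# The synthetic PCG simulator

No clinical recordings ship with the package; the simulator generates
labelled pediatric phonocardiograms so every stage is testable.

* **Timing.** Heart rate per record is uniform on 70–120 bpm (pediatric
  resting range, 4–7 cycles per 5 s), with log-normal per-cycle jitter
  (sd 0.03). The S1-onset→S2-onset interval follows the classical
  electromechanical-systole rule `0.55 − 0.0021·HR` seconds, so diastole
  shortens faster than systole as rate rises. Records open with a random
  partial diastole; ground-truth intervals tile the record exactly.
* **Sounds.** S1 and S2 are Gaussian-enveloped tone bursts (S1: 70–150 Hz,
  100 ms, amplitude 1.0; S2: 90–200 Hz, 80 ms, amplitude 0.6 — S1 louder and
  longer). ASD records get an accentuated (0.9) split S2 (45 ms split) plus
  a soft TR murmur; VSD records a harsh holosystolic band-noise murmur
  (100–300 Hz, amplitude 0.25); normals occasionally (p = 0.35) a soft
  innocent systolic murmur (amplitude 0.08), as is common in healthy
  children.
* **Variability.** Record-level log-normal draws (amplitudes sd 0.15,
  murmur amplitude sd 0.4, split sd 0.25) make class parameter ranges
  overlap, and per-cycle jitter (amplitudes sd 0.35, murmurs sd 0.7,
  frequencies sd 0.05) makes individual cycles ambiguous. This is the
  mechanism by which classification improves with the number of cycles per
  fragment: aggregating more cycles averages out per-cycle variation and
  recovers the record-level signature. White noise is added at 15 dB SNR by
  default.
* **What it does not emulate:** stethoscope transfer functions, pickup-mode
  differences, ambient/clothing artifacts, S3/S4 sounds, arrhythmias, and
  real inter-patient anatomy. Passing tests on this data demonstrate the
  pipeline's statistical machinery end to end, not clinical performance.

Classification-experiment recordings are simulated at 12 s so that
fragments up to 9 cycles exist for every recording (a 5-s record holds at
most ~7 complete cycles).

# Problem sizes and numerical choices

The built-in experiments run at desk scale: the segmentation experiment
trains a reduced model (16 channels, 32 LSTM units, 30 epochs) on 120
five-second records and evaluates 30 held-out records; the classification
sweep uses 60 twelve-second recordings (20 per class) with six-fold CV over
cycle counts 1–6. These sizes exercise every code path while keeping a full
run in minutes on one core; all sizes are arguments.

Other numerical choices: log floors `eps = 1e-8` (homomorphic) and `1e-10`
(mel energies); PCA component scales below `1e-12` are not divided by;
constant envelope channels standardize to zero rather than NaN; max-pool
ties resolve to the earlier frame; odd pooled lengths drop the last frame
(`floor(n/2)` windows); interpolation upsampling is endpoint-aligned linear.
Degenerate inputs (all-zero signals, single-class training sets, too few
cycles for a fragment) warn or error rather than producing silent nonsense.

# Known limitations

* The segmenter trains on CPU in R; it is deliberately small. Expect
  minutes, not seconds, for a hundred records, and scale widths/epochs
  accordingly.
* The cyclic-order projection in decoding is greedy, not a global optimum
  (no Viterbi/duration model — that is a different algorithm family by
  design).
* Tolerance crediting matches interval onsets; a prediction that fragments
  one true sound into several short intervals is only credited once.
* Simulator realism is intentionally limited (see above); numbers obtained
  on it do not transfer to clinical data.
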