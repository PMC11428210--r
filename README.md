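# pcgseg

Frame-wise segmentation of pediatric heart-sound recordings
(phonocardiograms, PCG) into the four cardiac states — **S1, systole, S2,
diastole** — and multi-classification of congenital heart disease
(**normal / ASD / VSD**) from fragments spanning an integer number of
cardiac cycles.

The package is aimed at biomedical-signal researchers who want a complete,
reproducible reference pipeline: every stage is an exported R function, every
stage is tested against independent brute-force oracles, and a built-in
simulator generates labelled synthetic phonocardiograms so the whole pipeline
runs without any clinical data.

## The models

**Segmentation — TBLSTM.** Four envelope features (Hilbert, homomorphic,
db6 level-3 wavelet detail, band power spectral density) at 50 frames/s feed
a multi-scale temporal convolutional network: five residual blocks of dilated
causal convolutions (dilation rates d = 2, 4, 8, 16, 16; left zero-padding
(K−1)·d; receptive field (K−1)·d+1) in a serial pyramid with max pooling
(window 2, stride 2) between blocks. Each block's pre-pool output is
interpolated back to the input frame count and the five scales are
concatenated, then a bidirectional LSTM

    i_t = σ(W_i[h_{t−1}, x_t] + b_i)        f_t = σ(W_f[h_{t−1}, x_t] + b_f)
    o_t = σ(W_o[h_{t−1}, x_t] + b_o)        C̃_t = tanh(W_C[h_{t−1}, x_t] + b_C)
    C_t = f_t ∗ C_{t−1} + i_t ∗ C̃_t         h_t = o_t ∗ tanh(C_t)

with dropout and a dense softmax head emits per-frame state posteriors.
Training (Adam, lr 0.001, batch 32, cross-entropy) uses hand-written
backpropagation in vectorized base R — no deep-learning framework is
required. Predictions are scored with tolerance windows (S1: 100 ms,
S2: 80 ms) and Acc/Se/P/F1 with macro averaging.

**Classification.** Decoded state sequences are cut into overlapping
fragments of N cardiac cycles (stride one cycle). Each fragment yields
13 MFCCs (26-filter mel bank over 30–500 Hz, DCT-II) plus Δ and ΔΔ —
39 dimensions per frame — aggregated to a 78-dimension mean/sd vector,
reduced by PCA (95 % variance, fitted per fold) and classified by a
100-tree random forest under recording-level six-fold cross-validation,
swept over N = 1…9 cycles.

## Worked example

```r
library(pcgseg)

# a labelled synthetic VSD record: 5 s at 2 kHz with exact state intervals
rec <- simulate_record(sim_profile("vsd"), duration_s = 5, seed = 42)
rec
#> <sim_record> class vsd, 115.7 bpm, 38 label intervals, seed 42
head(rec$labels, 3)
#>     start_s     end_s    state
#> 1 0.0000000 0.2034225 diastole
#> 2 0.2034225 0.2986680       S1
#> 3 0.2986680 0.5045585  systole

# envelope features and a quick segmenter (24 records, ~30 s on one core)
ds <- simulate_dataset(8, seed = 7)
feats <- lapply(ds$records, function(r) build_feature_matrix(r$signal))
labs  <- lapply(ds$records, function(r) labels_to_frames(r$labels, 250, 50))
cfg <- tblstm_config(channels = 16L, lstm_hidden = 32L, epochs = 60L, seed = 7L)
model <- train_segmenter(feats[1:21], labs[1:21], cfg)

pred <- decode_states(predict_states(model, feats[[22]]))
compute_metrics(tolerance_match(pred, labs[[22]]))
# pooled over the three held-out records:
#>      state    Acc     Se      P     F1
#> 1       S1 0.9413 0.7244 0.9109 0.8070
#> 2  systole 0.8653 0.8448 0.8014 0.8225
#> 3       S2 0.9333 0.5169 0.8679 0.6479
#> 4 diastole 0.9080 0.9586 0.8299 0.8896
#> macro: Acc=0.912  Se=0.7612  P=0.8525  F1=0.7918
```

Per-state rows report one-vs-rest accuracy, sensitivity, precision and F1
(S1/S2 scored with their tolerance windows); the macro line is the
unweighted mean over the four states. This deliberately small run already
separates the states; the full experiment below trains on 120 records and
reaches macro F1 ≈ 0.93.

The cycle-count experiment:

```r
ds  <- simulate_dataset(20, duration_s = 12, seed = 1)   # 60 recordings
sw  <- cross_validate_cycles(ds, cycle_range = 1:6, k = 6, seed = 1)
sw$summary   # Acc/Se/P/F1 plus per-class F1 for each cycle count
```

A thin command-line wrapper with `simulate`, `preprocess`, `envelopes`,
`train`, `segment`, `evaluate`, `fragment`, `features` and `sweep`
subcommands lives at `inst/cli/pcgseg.R`.

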