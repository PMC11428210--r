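# Shared fixtures built in code at test time.

tone <- function(freq, dur_s = 1, rate = 2000, amp = 1) {
  pcg_signal(amp * sin(2 * pi * freq * (seq_len(round(dur_s * rate)) - 0.5) /
                         rate), rate)
}

# a fixed-rate noiseless record for exact-timing tests
clean_record <- function(class = "normal", seed = 1, duration_s = 5,
                         bpm = 80) {
  prof <- sim_profile(class, heart_rate_bpm = c(bpm, bpm), hr_jitter_sd = 0,
                      noise_snr_db = Inf)
  simulate_record(prof, duration_s, seed = seed)
}

# tiny model configuration used across NN tests
tiny_config <- function(...) {
  args <- list(dilations = c(2L, 4L), channels = 3L, lstm_hidden = 4L,
               dropout_rate = 0, batch_size = 2L, epochs = 2L, seed = 7L)
  over <- list(...)
  args[names(over)] <- over
  do.call(tblstm_config, args)
}

# features + frame labels for a list of simulated records
prep_records <- function(records, frame_rate = 50) {
  feats <- lapply(records, function(r) build_feature_matrix(r$signal,
                                                            frame_rate))
  labs <- mapply(function(r, f) {
    labels_to_frames(r$labels, nrow(f$values), frame_rate)
  }, records, feats, SIMPLIFY = FALSE)
  list(features = feats, labels = labs)
}

# build a state_sequence from run-length (state, n_frames) pairs
seq_of_runs <- function(..., frame_rate = 50) {
  runs <- list(...)
  state_sequence(unlist(lapply(runs, function(r) rep(r[[1]], r[[2]]))),
                 frame_rate)
}
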