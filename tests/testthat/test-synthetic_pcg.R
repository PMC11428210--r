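test_that("labels tile the record exactly and alternate through the cycle", {
  for (cls in c("normal", "asd", "vsd")) {
    rec <- simulate_record(sim_profile(cls), duration_s = 5, seed = 31)
    lab <- rec$labels
    expect_equal(sum(lab$end_s - lab$start_s), 5, tolerance = 1e-9)
    expect_equal(lab$start_s[1], 0)
    expect_equal(lab$end_s[nrow(lab)], 5)
    expect_equal(lab$start_s[-1], lab$end_s[-nrow(lab)], tolerance = 1e-12)
    # the state after every S2 is diastole
    after_s2 <- which(lab$state == "S2") + 1L
    after_s2 <- after_s2[after_s2 <= nrow(lab)]
    expect_true(all(lab$state[after_s2] == "diastole"))
    expect_equal(length(rec$signal$samples), 10000L)
  }
})

test_that("a fixed 80 bpm heart gives 0.75 s cycles: six cycles span 4.5 s", {
  rec <- clean_record(bpm = 80, seed = 4)
  cyc <- true_cycles(rec)
  n_s1 <- sum(rec$labels$state == "S1")
  expect_equal(nrow(cyc), n_s1 - 1L)  # fence posts: onsets minus one
  expect_equal(unique(round(cyc$end_s - cyc$start_s, 9)), 0.75)
  s1_on <- rec$labels$start_s[rec$labels$state == "S1"]
  expect_gte(length(s1_on), 7L)
  expect_equal(s1_on[7] - s1_on[1], 4.5, tolerance = 1e-9)
})

test_that("records are bit-identical under one seed and differ across seeds", {
  p <- sim_profile("vsd")
  a <- simulate_record(p, 5, seed = 12)
  b <- simulate_record(p, 5, seed = 12)
  expect_identical(a$signal$samples, b$signal$samples)
  expect_identical(a$labels, b$labels)
  c_ <- simulate_record(p, 5, seed = 13)
  expect_false(identical(a$signal$samples, c_$signal$samples))
})

test_that("datasets are balanced with seeds derived from the master seed", {
  ds <- simulate_dataset(10, seed = 77)
  expect_length(ds$records, 30L)
  expect_equal(as.integer(table(ds$manifest$class)), rep(10L, 3))
  ds2 <- simulate_dataset(10, seed = 78)
  expect_false(identical(ds$records[[1]]$signal$samples,
                         ds2$records[[1]]$signal$samples))
  ds3 <- simulate_dataset(10, seed = 77)
  expect_identical(ds$records[[5]]$signal$samples,
                   ds3$records[[5]]$signal$samples)
})

test_that("S1 is louder and longer than S2 in normal records", {
  # jitter disabled: the comparison targets the design amplitudes (1.0 vs
  # 0.6), not a particular random draw
  prof <- sim_profile("normal", heart_rate_bpm = c(80, 80), hr_jitter_sd = 0,
                      noise_snr_db = Inf, amp_jitter_sd = 0,
                      record_amp_sd = 0, innocent_murmur_prob = 0)
  rec <- simulate_record(prof, 5, seed = 41)
  env <- hilbert_envelope(rec$signal)
  t <- (seq_along(env) - 0.5) / 2000
  in_state <- function(state) {
    lab <- rec$labels[rec$labels$state == state, ]
    sel <- rep(FALSE, length(t))
    for (i in seq_len(nrow(lab))) sel <- sel | (t >= lab$start_s[i] &
                                                  t < lab$end_s[i])
    sel
  }
  s1_dur <- sum(with(rec$labels, end_s - start_s)[rec$labels$state == "S1"])
  s2_dur <- sum(with(rec$labels, end_s - start_s)[rec$labels$state == "S2"])
  expect_gt(s1_dur, s2_dur)
  expect_gt(max(env[in_state("S1")]), max(env[in_state("S2")]))
})

test_that("VSD records carry at least 3x the systolic band energy of normals", {
  band_energy <- function(rec) {
    bf <- signal::butter(2, c(100, 300) / 1000, type = "pass")
    y <- signal::filtfilt(bf, rec$signal$samples)
    t <- (seq_along(y) - 0.5) / 2000
    lab <- rec$labels[rec$labels$state == "systole", ]
    sel <- rep(FALSE, length(t))
    for (i in seq_len(nrow(lab))) sel <- sel | (t >= lab$start_s[i] &
                                                  t < lab$end_s[i])
    mean(y[sel]^2)
  }
  e_vsd <- mean(vapply(1:6, function(s)
    band_energy(simulate_record(sim_profile("vsd"), 5, seed = s)), 0))
  e_norm <- mean(vapply(1:6, function(s)
    band_energy(simulate_record(sim_profile("normal"), 5, seed = 100 + s)), 0))
  expect_gte(e_vsd, 3 * e_norm)
})

test_that("a split S2 shows two envelope maxima inside S2 intervals", {
  prof <- sim_profile("asd", noise_snr_db = Inf, tr_murmur = FALSE,
                      amp_jitter_sd = 0, murmur_jitter_sd = 0)
  rec <- simulate_record(prof, 5, seed = 8)
  env <- hilbert_envelope(rec$signal)
  s2 <- rec$labels[rec$labels$state == "S2", ]
  n_bimodal <- 0L
  for (i in seq_len(nrow(s2))) {
    i0 <- max(1L, floor(s2$start_s[i] * 2000)); i1 <- ceiling(s2$end_s[i] * 2000)
    seg <- env[i0:i1]
    # count strict local maxima above a fifth of the segment peak
    loc <- which(diff(sign(diff(seg))) == -2) + 1L
    loc <- loc[seg[loc] > 0.2 * max(seg)]
    # merge maxima closer than 10 ms (ripples of one lobe)
    if (length(loc) > 1L) loc <- loc[c(TRUE, diff(loc) > 20)]
    if (length(loc) >= 2L) n_bimodal <- n_bimodal + 1L
  }
  expect_gte(n_bimodal, ceiling(nrow(s2) / 2))
})

test_that("infeasible timing profiles raise a parameter error", {
  prof <- sim_profile("normal", s1 = list(duration_ms = 500),
                      s2 = list(duration_ms = 400),
                      heart_rate_bpm = c(150, 150))
  expect_error(simulate_record(prof, 5, seed = 1), "infeasible|exceed")
})
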