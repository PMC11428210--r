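# Labelled synthetic pediatric phonocardiograms. S1/S2 are Gaussian-enveloped
# band-limited tone bursts (S1 louder and longer than S2); ASD records get an
# accentuated, split S2 and a soft tricuspid-regurgitation systolic murmur;
# VSD records get a harsh holosystolic band-noise murmur. Per-cycle jitter of
# heart rate, burst amplitudes, frequencies and S2 split makes single cycles
# ambiguous while record-level signatures remain recoverable by aggregating
# several cycles. Ground-truth state intervals tile the record exactly.

#' Simulation profile for one diagnostic class
#'
#' @param class `"normal"`, `"asd"` or `"vsd"` (class-specific defaults), or
#'   `"custom"`.
#' @param heart_rate_bpm Two-element resting heart-rate range; one value per
#'   record is drawn uniformly from it.
#' @param hr_jitter_sd Per-cycle multiplicative log-normal heart-rate jitter.
#' @param s1,s2 Lists with `freq_hz` (range), `duration_ms`, `amp`; `s2`
#'   additionally `split_ms` (0 = no split).
#' @param murmur List with `type` (`"none"`, `"holosystolic"`,
#'   `"diastolic_flow"`), `band` (Hz range), `amp`.
#' @param tr_murmur Add a soft tricuspid-regurgitation systolic murmur.
#' @param noise_snr_db Additive white-noise SNR in dB (`Inf` = noiseless).
#' @param amp_jitter_sd Per-cycle log-normal amplitude jitter of S1/S2.
#' @param murmur_jitter_sd Per-cycle log-normal amplitude jitter of murmurs.
#' @param record_amp_sd,record_murmur_sd,record_split_sd Record-level
#'   log-normal spreads of the S1/S2 amplitudes, murmur amplitude and S2
#'   split; these make class parameter ranges overlap across records, so no
#'   single feature separates the classes deterministically.
#' @param innocent_murmur_prob Probability that a record adds a soft
#'   (amplitude 0.08) innocent systolic murmur — common in healthy children.
#' @return A `sim_profile` list.
#' @export
sim_profile <- function(class = c("normal", "asd", "vsd", "custom"),
                        heart_rate_bpm = c(70, 120), hr_jitter_sd = 0.03,
                        s1 = NULL, s2 = NULL, murmur = NULL, tr_murmur = NULL,
                        noise_snr_db = 15, amp_jitter_sd = 0.35,
                        murmur_jitter_sd = 0.7, record_amp_sd = 0.15,
                        record_murmur_sd = 0.4, record_split_sd = 0.25,
                        innocent_murmur_prob = NULL) {
  class <- match.arg(class)
  def_s1 <- list(freq_hz = c(70, 150), duration_ms = 100, amp = 1.0)
  def_s2 <- switch(class,
    asd = list(freq_hz = c(90, 200), duration_ms = 90, amp = 0.90,
               split_ms = 45),
    list(freq_hz = c(90, 200), duration_ms = 80, amp = 0.6, split_ms = 0))
  def_murmur <- switch(class,
    vsd = list(type = "holosystolic", band = c(100, 300), amp = 0.25),
    list(type = "none", band = c(100, 300), amp = 0))
  def_tr <- class == "asd"
  def_innocent <- if (class == "normal") 0.35 else 0
  merge_list <- function(def, usr) {
    if (is.null(usr)) return(def)
    def[names(usr)] <- usr
    def
  }
  p <- list(class = class,
            heart_rate_bpm = heart_rate_bpm, hr_jitter_sd = hr_jitter_sd,
            s1 = merge_list(def_s1, s1), s2 = merge_list(def_s2, s2),
            murmur = merge_list(def_murmur, murmur),
            tr_murmur = if (is.null(tr_murmur)) def_tr else isTRUE(tr_murmur),
            noise_snr_db = noise_snr_db, amp_jitter_sd = amp_jitter_sd,
            murmur_jitter_sd = murmur_jitter_sd,
            record_amp_sd = record_amp_sd,
            record_murmur_sd = record_murmur_sd,
            record_split_sd = record_split_sd,
            innocent_murmur_prob = if (is.null(innocent_murmur_prob))
              def_innocent else innocent_murmur_prob)
  stopifnot(p$s1$duration_ms > 0, p$s2$duration_ms > 0, p$s1$amp >= 0,
            p$s2$amp >= 0, p$murmur$amp >= 0)
  structure(p, class = "sim_profile")
}

# Gaussian-enveloped tone burst added in place
add_burst <- function(x, rate, center_s, dur_s, freq, amp, phase) {
  sigma <- dur_s / 6
  i0 <- max(1L, floor((center_s - dur_s / 2) * rate) + 1L)
  i1 <- min(length(x), ceiling((center_s + dur_s / 2) * rate))
  if (i1 < i0) return(x)
  t <- (i0:i1 - 0.5) / rate
  x[i0:i1] <- x[i0:i1] +
    amp * exp(-0.5 * ((t - center_s) / sigma)^2) * sin(2 * pi * freq * t + phase)
  x
}

# flat-top window with raised-cosine ramps, over [t0, t1]
soft_window <- function(n, rate, t0, t1, ramp_s = 0.012) {
  w <- numeric(n)
  i0 <- max(1L, floor(t0 * rate) + 1L)
  i1 <- min(n, ceiling(t1 * rate))
  if (i1 < i0) return(w)
  t <- (i0:i1 - 0.5) / rate
  ramp <- pmax(0, pmin(1, pmin(t - t0, t1 - t) / ramp_s))
  w[i0:i1] <- sin(0.5 * pi * ramp)^2
  w
}

#' Simulate one labelled heart-sound record
#'
#' Cycle timing: the S1-onset-to-S2-onset (electromechanical systole)
#' interval follows `0.55 - 0.0021 * HR` seconds, so diastole shortens faster
#' than systole as the rate rises; each cycle's rate gets log-normal jitter.
#' The record opens with a random partial diastole so cycle phase varies
#' across records. Ground-truth intervals tile `[0, duration_s]` exactly.
#'
#' @param profile A [sim_profile].
#' @param duration_s Record length in seconds (default 5).
#' @param seed RNG seed; the record is a deterministic function of
#'   (profile, duration_s, seed, rate).
#' @param rate Sampling rate in Hz (default 2000).
#' @return A `sim_record`: list with `signal` ([pcg_signal]), `labels`
#'   ([interval_labels]), `class`, `seed`, `heart_rate_bpm`.
#' @export
simulate_record <- function(profile, duration_s = 5, seed = 1L, rate = 2000) {
  stopifnot(inherits(profile, "sim_profile"), duration_s > 0)
  set.seed(seed)
  n <- round(duration_s * rate)
  x <- numeric(n)

  hr <- stats::runif(1, profile$heart_rate_bpm[1], profile$heart_rate_bpm[2])
  f1 <- stats::runif(1, profile$s1$freq_hz[1], profile$s1$freq_hz[2])
  f2 <- stats::runif(1, profile$s2$freq_hz[1], profile$s2$freq_hz[2])

  # record-level parameter draws: class parameter ranges overlap across
  # records, so classification cannot key on a single deterministic feature
  a1_rec <- profile$s1$amp * exp(stats::rnorm(1, 0, profile$record_amp_sd))
  a2_rec <- profile$s2$amp * exp(stats::rnorm(1, 0, profile$record_amp_sd))
  murmur_amp_rec <- profile$murmur$amp *
    exp(stats::rnorm(1, 0, profile$record_murmur_sd))
  split_rec <- profile$s2$split_ms *
    exp(stats::rnorm(1, 0, profile$record_split_sd))
  tr_amp_rec <- 0.12 * exp(stats::rnorm(1, 0, profile$record_murmur_sd))
  innocent <- stats::runif(1) < profile$innocent_murmur_prob
  innocent_amp_rec <- 0.08 * exp(stats::rnorm(1, 0, profile$record_murmur_sd))

  seg_start <- numeric(0); seg_end <- numeric(0); seg_state <- character(0)
  push <- function(t0, t1, state) {
    if (t1 > t0 + 1e-9) {
      seg_start <<- c(seg_start, t0); seg_end <<- c(seg_end, t1)
      seg_state <<- c(seg_state, state)
    }
  }

  # murmur noise carriers (unit RMS, full length) reused across cycles
  make_carrier <- function(band) {
    bf <- signal::butter(2, pmin(band / (rate / 2), 0.99), type = "pass")
    v <- signal::filtfilt(bf, stats::rnorm(n))
    v / max(stats::sd(v), 1e-12)
  }
  carrier_m <- if (profile$murmur$type != "none") make_carrier(profile$murmur$band)
  carrier_tr <- if (profile$tr_murmur) make_carrier(c(120, 250))
  carrier_in <- if (innocent) make_carrier(c(100, 220))

  t <- stats::runif(1, 0, 0.25)  # leading partial diastole
  if (t > 0) push(0, t, "diastole")
  d1_base <- profile$s1$duration_ms / 1000
  d2_base <- profile$s2$duration_ms / 1000

  while (TRUE) {
    hr_c <- hr * exp(stats::rnorm(1, 0, profile$hr_jitter_sd))
    cyc <- 60 / hr_c
    qs2 <- 0.55 - 0.0021 * hr_c             # S1 onset -> S2 onset
    d1 <- d1_base * exp(stats::rnorm(1, 0, 0.08))
    d2 <- d2_base * exp(stats::rnorm(1, 0, 0.08))
    sys_d <- qs2 - d1
    dia_d <- cyc - qs2 - d2
    if (sys_d <= 0.05 || dia_d <= 0.05) {
      stop("infeasible cycle timing: sound durations exceed the cycle",
           call. = FALSE)
    }
    if (t >= duration_s) break

    a1 <- a1_rec * exp(stats::rnorm(1, 0, profile$amp_jitter_sd))
    a2 <- a2_rec * exp(stats::rnorm(1, 0, profile$amp_jitter_sd))
    x <- add_burst(x, rate, t + d1 / 2, d1, f1 * exp(stats::rnorm(1, 0, 0.05)),
                   a1, stats::runif(1, 0, 2 * pi))
    s2_mid <- t + d1 + sys_d + d2 / 2
    split <- split_rec / 1000 * exp(stats::rnorm(1, 0, 0.25))
    if (split > 0.015) {
      sub_d <- max(d2 - split, 0.03)
      x <- add_burst(x, rate, s2_mid - split / 2, sub_d,
                     f2 * exp(stats::rnorm(1, 0, 0.05)), a2,
                     stats::runif(1, 0, 2 * pi))
      x <- add_burst(x, rate, s2_mid + split / 2, sub_d,
                     f2 * 1.1 * exp(stats::rnorm(1, 0, 0.05)), 0.85 * a2,
                     stats::runif(1, 0, 2 * pi))
    } else {
      x <- add_burst(x, rate, s2_mid, d2, f2 * exp(stats::rnorm(1, 0, 0.05)),
                     a2, stats::runif(1, 0, 2 * pi))
    }
    sys0 <- t + d1; sys1 <- t + d1 + sys_d
    if (profile$murmur$type == "holosystolic") {
      am <- murmur_amp_rec * exp(stats::rnorm(1, 0, profile$murmur_jitter_sd))
      x <- x + am * carrier_m * soft_window(n, rate, sys0, sys1)
    } else if (profile$murmur$type == "diastolic_flow") {
      am <- murmur_amp_rec * exp(stats::rnorm(1, 0, profile$murmur_jitter_sd))
      x <- x + am * carrier_m * soft_window(n, rate, sys1 + d2, min(t + cyc, duration_s))
    }
    if (profile$tr_murmur) {
      am <- tr_amp_rec * exp(stats::rnorm(1, 0, profile$murmur_jitter_sd))
      x <- x + am * carrier_tr * soft_window(n, rate, sys0, sys1)
    }
    if (innocent) {
      am <- innocent_amp_rec * exp(stats::rnorm(1, 0, profile$murmur_jitter_sd))
      x <- x + am * carrier_in * soft_window(n, rate, sys0, sys1)
    }

    push(t, t + d1, "S1")
    push(t + d1, sys1, "systole")
    push(sys1, sys1 + d2, "S2")
    push(sys1 + d2, t + cyc, "diastole")
    t <- t + cyc
  }

  # truncate the label tiling at the record end
  keep <- seg_start < duration_s - 1e-9
  seg_start <- seg_start[keep]; seg_end <- pmin(seg_end[keep], duration_s)
  seg_state <- seg_state[keep]

  if (is.finite(profile$noise_snr_db)) {
    p_sig <- mean(x^2)
    if (p_sig > 0) {
      p_noise <- p_sig / 10^(profile$noise_snr_db / 10)
      x <- x + stats::rnorm(n, sd = sqrt(p_noise))
    }
  }

  structure(list(
    signal = pcg_signal(x, rate, sprintf("sim:%s:seed%d", profile$class, seed)),
    labels = interval_labels(seg_start, seg_end, seg_state),
    class = profile$class, seed = as.integer(seed), heart_rate_bpm = hr),
    class = "sim_record")
}

#' @export
print.sim_record <- function(x, ...) {
  cat(sprintf("<sim_record> class %s, %.1f bpm, %d label intervals, seed %d\n",
              x$class, x$heart_rate_bpm, nrow(x$labels), x$seed))
  invisible(x)
}

#' Simulate a balanced labelled dataset
#'
#' Per-record seeds are drawn from the master seed, so the whole dataset is a
#' deterministic function of its arguments.
#'
#' @param n_per_class Records per class (>= 1).
#' @param classes Character vector of classes to include.
#' @param duration_s Record length in seconds.
#' @param seed Master seed.
#' @param profiles Optional named list of [sim_profile]s overriding the
#'   class defaults.
#' @param rate Sampling rate in Hz.
#' @return A `pcg_dataset`: list with `records` (list of `sim_record`) and
#'   `manifest` (data frame `record_id`, `class`, `seed`, `duration_s`,
#'   `heart_rate_bpm`).
#' @export
simulate_dataset <- function(n_per_class, classes = c("normal", "asd", "vsd"),
                             duration_s = 5, seed = 1L, profiles = NULL,
                             rate = 2000) {
  stopifnot(n_per_class >= 1L)
  set.seed(seed)
  cls <- rep(classes, each = n_per_class)
  seeds <- sample.int(.Machine$integer.max - 1L, length(cls))
  records <- vector("list", length(cls))
  for (i in seq_along(cls)) {
    prof <- if (!is.null(profiles) && cls[i] %in% names(profiles)) {
      profiles[[cls[i]]]
    } else {
      sim_profile(cls[i])
    }
    records[[i]] <- simulate_record(prof, duration_s, seeds[i], rate)
  }
  manifest <- data.frame(
    record_id = sprintf("%s_%03d", cls, stats::ave(seq_along(cls), cls,
                                                   FUN = seq_along)),
    class = cls, seed = seeds, duration_s = duration_s,
    heart_rate_bpm = vapply(records, `[[`, 0, "heart_rate_bpm"),
    stringsAsFactors = FALSE)
  structure(list(records = records, manifest = manifest),
            class = "pcg_dataset")
}

#' @export
print.pcg_dataset <- function(x, ...) {
  cat(sprintf("<pcg_dataset> %d records (%s)\n", nrow(x$manifest),
              paste(sprintf("%s: %d", names(table(x$manifest$class)),
                            table(x$manifest$class)), collapse = ", ")))
  invisible(x)
}

#' Ground-truth cardiac cycles of a simulated record
#'
#' Cycle boundaries are the S1 interval onsets of the ground-truth labels.
#' @param record A `sim_record` (or [interval_labels]).
#' @return Data frame `start_s`, `end_s`, one row per complete cycle.
#' @export
true_cycles <- function(record) {
  labels <- if (inherits(record, "sim_record")) record$labels else record
  on <- labels$start_s[labels$state == "S1"]
  if (length(on) < 2L) return(data.frame(start_s = numeric(0), end_s = numeric(0)))
  data.frame(start_s = on[-length(on)], end_s = on[-1L])
}
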