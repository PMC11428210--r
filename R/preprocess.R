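# Standardized pre-processing: Butterworth band-pass (zero-phase), resampling
# to a common rate, maximum normalization.

#' Zero-phase Butterworth band-pass filter
#'
#' A second-order (by default) Butterworth band-pass applied forward and
#' backward (`signal::filtfilt`), so the effective magnitude order doubles and
#' the group delay is zero — heart-sound event timings are not shifted, which
#' the downstream tolerance-window evaluation (±80–100 ms) relies on.
#'
#' @param signal A [pcg_signal].
#' @param low,high Band edges in Hz; defaults 25 and 400.
#' @param order Butterworth design order of each pass (default 2).
#' @return Filtered [pcg_signal], same length and rate.
#' @export
pcg_bandpass <- function(signal, low = 25, high = 400, order = 2) {
  stopifnot(inherits(signal, "pcg_signal"))
  nyq <- signal$rate / 2
  if (!(low > 0 && low < high)) stop("need 0 < low < high", call. = FALSE)
  if (high >= nyq) {
    stop(sprintf("high edge (%g Hz) must be below Nyquist (%g Hz)", high, nyq),
         call. = FALSE)
  }
  if (!length(signal$samples)) return(signal)
  bf <- signal::butter(order, c(low, high) / nyq, type = "pass")
  y <- signal::filtfilt(bf, signal$samples)
  pcg_signal(y, signal$rate, signal$source_id)
}

#' Resample a signal to a target rate
#'
#' Anti-aliased polyphase resampling via `signal::resample` on the rational
#' ratio `target_rate / rate`. A no-op when the rates already match.
#'
#' @param signal A [pcg_signal].
#' @param target_rate Target rate in Hz (default 2000).
#' @return Resampled [pcg_signal] whose duration matches the input within one
#'   sample period.
#' @export
pcg_resample <- function(signal, target_rate = 2000) {
  stopifnot(inherits(signal, "pcg_signal"), target_rate > 0)
  if (signal$rate == target_rate) return(signal)
  fr <- ratio_approx(target_rate / signal$rate)
  y <- signal::resample(signal$samples, p = fr[1], q = fr[2])
  n_out <- round(length(signal$samples) * target_rate / signal$rate)
  # resample can over/under-run by a sample at the tail; pin the length
  if (length(y) > n_out) y <- y[seq_len(n_out)]
  if (length(y) < n_out) y <- c(y, rep(y[length(y)], n_out - length(y)))
  pcg_signal(y, target_rate, signal$source_id)
}

# small continued-fraction rational approximation p/q of a positive ratio
ratio_approx <- function(x, tol = 1e-9, max_den = 1e6) {
  p0 <- 0; q0 <- 1; p1 <- 1; q1 <- 0; r <- x
  repeat {
    a <- floor(r)
    p <- a * p1 + p0; q <- a * q1 + q0
    if (q > max_den || abs(p / q - x) < tol * x) return(c(p, q))
    p0 <- p1; q0 <- q1; p1 <- p; q1 <- q
    r <- 1 / (r - a)
  }
}

#' Maximum normalization
#'
#' Divides by `max(abs(samples))`. All-zero input is returned unchanged with
#' a warning.
#'
#' @param signal A [pcg_signal].
#' @return Normalized [pcg_signal] with `max(abs(samples)) == 1` (unless all
#'   zero).
#' @export
normalize_max <- function(signal) {
  stopifnot(inherits(signal, "pcg_signal"))
  m <- max(abs(signal$samples), 0)
  if (m == 0) {
    warning("all-zero signal: normalize_max is a no-op", call. = FALSE)
    return(signal)
  }
  pcg_signal(signal$samples / m, signal$rate, signal$source_id)
}

#' Standard pre-processing chain
#'
#' Band-pass (zero-phase Butterworth), then resample to `rate`, then maximum
#' normalization. `filter_first = FALSE` swaps the first two steps.
#'
#' @param signal A [pcg_signal].
#' @param low,high Band edges in Hz (defaults 25, 400).
#' @param rate Target sampling rate in Hz (default 2000).
#' @param order Butterworth order per pass.
#' @param filter_first Filter at the native rate before resampling (default
#'   `TRUE`).
#' @return Pre-processed [pcg_signal] at `rate` with unit peak amplitude.
#' @export
preprocess <- function(signal, low = 25, high = 400, rate = 2000, order = 2,
                       filter_first = TRUE) {
  stopifnot(inherits(signal, "pcg_signal"))
  if (filter_first) {
    signal <- pcg_bandpass(signal, low, high, order)
    signal <- pcg_resample(signal, rate)
  } else {
    signal <- pcg_resample(signal, rate)
    signal <- pcg_bandpass(signal, low, high, order)
  }
  normalize_max(signal)
}
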