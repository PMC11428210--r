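# The four envelope features driving the segmenter: Hilbert, homomorphic,
# wavelet (db6 level-3 detail) and power-spectral-density envelopes, plus the
# frame-aligned, per-channel standardized feature matrix.

analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[1L] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1L] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Hilbert envelope
#'
#' `mode = "analytic"` (default) returns the magnitude of the analytic signal
#' `|x + iH{x}|`, the standard amplitude envelope. `mode = "literal"` returns
#' `|H{x}|`, the plain absolute value of the Hilbert transform.
#'
#' @param signal A [pcg_signal] (or numeric vector).
#' @param mode `"analytic"` or `"literal"`.
#' @return Non-negative numeric vector, same length as the input.
#' @export
hilbert_envelope <- function(signal, mode = c("analytic", "literal")) {
  mode <- match.arg(mode)
  x <- if (inherits(signal, "pcg_signal")) signal$samples else as.numeric(signal)
  if (length(x) < 2L) return(abs(x))
  a <- analytic_signal(x)
  if (mode == "analytic") Mod(a) else abs(Im(a))
}

#' Homomorphic envelope
#'
#' `exp(LPF(log(|analytic| + eps)))` with a first-order zero-phase Butterworth
#' low-pass. The default 8 Hz cutoff smooths the within-sound oscillation while
#' keeping S1/S2 bursts separated.
#'
#' @param signal A [pcg_signal].
#' @param lp_cutoff Low-pass cutoff in Hz (default 8).
#' @param eps Log floor guarding silent stretches.
#' @return Non-negative numeric vector, same length as the input.
#' @export
homomorphic_envelope <- function(signal, lp_cutoff = 8, eps = 1e-8) {
  stopifnot(inherits(signal, "pcg_signal"))
  if (lp_cutoff >= signal$rate / 2) {
    stop("lp_cutoff must be below Nyquist", call. = FALSE)
  }
  mag <- hilbert_envelope(signal, "analytic")
  if (all(mag == 0)) return(rep(eps, length(mag)))  # silent record: eps floor
  bf <- signal::butter(1, lp_cutoff / (signal$rate / 2), type = "low")
  exp(signal::filtfilt(bf, log(mag + eps)))
}

#' Wavelet envelope (db6 level-3 detail)
#'
#' Three-level periodized db6 decomposition; the envelope is the absolute
#' value of the level-3 detail band. `mode = "reconstruct"` (default) inverts
#' the transform with only that band retained, so the envelope shares the
#' signal's time axis; `mode = "coefficients"` returns the raw decimated
#' coefficients (length about N/8). At 2 kHz the level-3 detail band covers
#' 125–250 Hz.
#'
#' @param signal A [pcg_signal].
#' @param mode `"reconstruct"` or `"coefficients"`.
#' @return Non-negative numeric vector.
#' @export
wavelet_envelope <- function(signal, mode = c("reconstruct", "coefficients")) {
  mode <- match.arg(mode)
  x <- if (inherits(signal, "pcg_signal")) signal$samples else as.numeric(signal)
  if (length(x) < 8L * length(db6_dec_lo)) {
    stop("signal too short for a level-3 db6 decomposition", call. = FALSE)
  }
  dec <- dwt_multilevel(x, 3L)
  if (mode == "coefficients") return(abs(dec$d[[3L]]))
  abs(dwt_reconstruct_detail(dec, 3L)[seq_along(x)])
}

#' Power spectral density envelope
#'
#' Hamming-windowed short-time periodograms (window 0.05 s, 50% overlap by
#' default); the envelope value of a window is its mean power spectral density
#' over `band` (default 40–60 Hz, where S1/S2 energy dominates).
#'
#' @param signal A [pcg_signal].
#' @param win_s Window length in seconds.
#' @param overlap Fractional overlap in `[0, 1)`.
#' @param band Two-element Hz range.
#' @return Non-negative vector, one value per window
#'   (`floor((N - W)/hop) + 1` windows).
#' @export
psd_envelope <- function(signal, win_s = 0.05, overlap = 0.5,
                         band = c(40, 60)) {
  stopifnot(inherits(signal, "pcg_signal"))
  W <- round(win_s * signal$rate)
  if (W < 8L) stop("window too short: need win_s * rate >= 8", call. = FALSE)
  if (band[2] > signal$rate / 2 || band[1] < 0 || band[1] >= band[2]) {
    stop("band must lie within [0, Nyquist]", call. = FALSE)
  }
  hop <- max(1L, round(W * (1 - overlap)))
  x <- signal$samples
  n_win <- floor((length(x) - W) / hop) + 1L
  if (n_win < 1L) stop("signal shorter than one window", call. = FALSE)
  win <- signal::hamming(W)
  starts <- (seq_len(n_win) - 1L) * hop
  frames <- matrix(x[outer(seq_len(W), starts, `+`)], nrow = W) * win
  spec <- Mod(stats::mvfft(frames))^2 / (signal$rate * sum(win^2))
  freqs <- (seq_len(W) - 1L) / W * signal$rate
  sel <- which(freqs >= band[1] & freqs <= band[2])
  if (!length(sel)) sel <- which.min(abs(freqs - mean(band)))
  colMeans(spec[sel, , drop = FALSE])
}

#' Build the frame-aligned feature matrix for the segmenter
#'
#' Computes the four envelopes, linearly interpolates each onto a common
#' grid of `ceil(duration * frame_rate)` frame centers, and standardizes each
#' channel to zero mean and unit variance over the record (constant channels
#' become all-zero).
#'
#' @param signal A pre-processed [pcg_signal].
#' @param frame_rate Frames per second (default 50, i.e. 20 ms frames).
#' @param hilbert_mode Passed to [hilbert_envelope()].
#' @param psd_band Passed to [psd_envelope()].
#' @return A `pcg_features` object: list with `values` (frames x 4 matrix),
#'   `frame_rate` and `channel_names`.
#' @export
build_feature_matrix <- function(signal, frame_rate = 50,
                                 hilbert_mode = "analytic",
                                 psd_band = c(40, 60)) {
  stopifnot(inherits(signal, "pcg_signal"))
  n <- length(signal$samples)
  dur <- n / signal$rate
  n_frames <- ceiling(dur * frame_rate)
  centers <- (seq_len(n_frames) - 0.5) / frame_rate

  t_sample <- (seq_len(n) - 0.5) / signal$rate
  hil <- hilbert_envelope(signal, hilbert_mode)
  hom <- homomorphic_envelope(signal)
  wav <- wavelet_envelope(signal)
  psd <- psd_envelope(signal, band = psd_band)
  hop_s <- 0.5 * 0.05  # psd window hop (50% overlap of 0.05 s)
  t_psd <- (seq_along(psd) - 1L) * hop_s + 0.025

  interp <- function(tx, y) {
    stats::approx(tx, y, xout = centers, rule = 2)$y
  }
  vals <- cbind(
    hilbert     = interp(t_sample, hil),
    homomorphic = interp(t_sample, hom),
    wavelet     = interp(t_sample, wav),
    psd         = interp(t_psd, psd)
  )
  vals <- apply(vals, 2L, function(v) {
    s <- stats::sd(v)
    if (!is.finite(s) || s < 1e-12) rep(0, length(v)) else (v - mean(v)) / s
  })
  structure(list(values = vals, frame_rate = frame_rate,
                 channel_names = colnames(vals)),
            class = "pcg_features")
}

#' @export
print.pcg_features <- function(x, ...) {
  cat(sprintf("<pcg_features> %d frames x %d channels @ %g frames/s\n",
              nrow(x$values), ncol(x$values), x$frame_rate))
  invisible(x)
}
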