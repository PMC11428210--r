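# MFCC + delta + delta-delta features: Hamming framing, FFT power spectrum,
# 26-filter triangular mel bank over 30-500 Hz, log, orthonormal DCT-II,
# regression deltas; fragment-level mean/sd aggregation and PCA reduction.

hz_to_mel <- function(f) 2595 * log10(1 + f / 700)
mel_to_hz <- function(m) 700 * (10^(m / 2595) - 1)

#' Cut a signal into Hamming-windowed frames
#'
#' @param signal A [pcg_signal].
#' @param frame_ms Frame length in ms (default 20).
#' @param hop_ms Frame shift in ms (default 10).
#' @return Matrix of `floor((N - W)/hop) + 1` rows (frames) by `W` columns,
#'   each row windowed; zero rows (with warning) when the signal is shorter
#'   than one frame.
#' @export
frame_signal <- function(signal, frame_ms = 20, hop_ms = 10) {
  stopifnot(inherits(signal, "pcg_signal"))
  W <- round(frame_ms * signal$rate / 1000)
  hop <- max(1L, round(hop_ms * signal$rate / 1000))
  x <- signal$samples
  if (length(x) < W) {
    warning("signal shorter than one frame: no frames", call. = FALSE)
    return(matrix(numeric(0), 0L, W))
  }
  n_frames <- floor((length(x) - W) / hop) + 1L
  starts <- (seq_len(n_frames) - 1L) * hop
  fr <- matrix(x[outer(starts, seq_len(W), `+`)], nrow = n_frames)
  fr * matrix(signal::hamming(W), n_frames, W, byrow = TRUE)
}

#' Triangular mel filterbank
#'
#' `n_filters` triangular filters with centers equally spaced on the mel
#' scale between `fmin` and `fmax`; adjacent filters overlap and every
#' filter's support lies within the band.
#'
#' @param rate Sampling rate in Hz.
#' @param n_filters Number of filters (default 26).
#' @param fmin,fmax Band edges in Hz (defaults 30 and 500).
#' @param nfft FFT size (default 256; zero-padded frames).
#' @return A `mel_filterbank`: list with `weights`
#'   (`n_filters` x `nfft/2 + 1` matrix), `centers_hz`, `nfft`, `rate`.
#' @export
mel_filterbank <- function(rate, n_filters = 26L, fmin = 30, fmax = 500,
                           nfft = 256L) {
  if (fmax > rate / 2) stop("fmax above Nyquist", call. = FALSE)
  edges_mel <- seq(hz_to_mel(fmin), hz_to_mel(fmax), length.out = n_filters + 2L)
  edges_hz <- mel_to_hz(edges_mel)
  bin_hz <- (seq_len(nfft %/% 2L + 1L) - 1L) * rate / nfft
  Wt <- matrix(0, n_filters, length(bin_hz))
  for (i in seq_len(n_filters)) {
    lo <- edges_hz[i]; mid <- edges_hz[i + 1L]; hi <- edges_hz[i + 2L]
    up <- (bin_hz - lo) / (mid - lo)
    down <- (hi - bin_hz) / (hi - mid)
    Wt[i, ] <- pmax(0, pmin(up, down))
  }
  structure(list(weights = Wt, centers_hz = edges_hz[2:(n_filters + 1L)],
                 nfft = as.integer(nfft), rate = rate,
                 fmin = fmin, fmax = fmax),
            class = "mel_filterbank")
}

# orthonormal DCT-II matrix (n_out x n_in)
dct2_matrix <- function(n_out, n_in) {
  D <- matrix(0, n_out, n_in)
  for (k in seq_len(n_out)) {
    D[k, ] <- cos(pi * (k - 1) * (seq_len(n_in) - 0.5) / n_in)
  }
  D <- D * sqrt(2 / n_in)
  D[1L, ] <- D[1L, ] / sqrt(2)
  D
}

#' MFCCs of windowed frames
#'
#' Per frame: zero-padded FFT power spectrum, mel filterbank energies,
#' log (with floor `eps`), orthonormal DCT-II; coefficients `c0..c12` by
#' default (order 12 plus the energy coefficient, 13 columns). Set
#' `drop_c0 = TRUE` to discard the energy coefficient.
#'
#' @param frames Frames-by-samples matrix from [frame_signal()].
#' @param bank A [mel_filterbank] matching the signal's rate.
#' @param n_coeffs Number of cepstral coefficients (default 13).
#' @param drop_c0 Drop `c0` (default `FALSE`).
#' @param eps Log floor for silent frames.
#' @return Frames-by-`n_coeffs` matrix.
#' @export
mfcc_frames <- function(frames, bank, n_coeffs = 13L, drop_c0 = FALSE,
                        eps = 1e-10) {
  stopifnot(inherits(bank, "mel_filterbank"))
  if (!nrow(frames)) return(matrix(numeric(0), 0L, n_coeffs))
  nfft <- bank$nfft
  if (ncol(frames) > nfft) stop("frame longer than nfft", call. = FALSE)
  padded <- cbind(frames, matrix(0, nrow(frames), nfft - ncol(frames)))
  spec <- Mod(stats::mvfft(t(padded)))^2
  spec <- spec[seq_len(nfft %/% 2L + 1L), , drop = FALSE]
  fb <- log(pmax(bank$weights %*% spec, eps))       # n_filters x frames
  n_take <- if (drop_c0) n_coeffs + 1L else n_coeffs
  D <- dct2_matrix(n_take, nrow(fb))
  cep <- t(D %*% fb)
  if (drop_c0) cep[, -1L, drop = FALSE] else cep
}

#' MFCCs of a signal
#'
#' Convenience wrapper: [frame_signal()] then [mfcc_frames()].
#' @inheritParams frame_signal
#' @inheritParams mfcc_frames
#' @param n_filters,fmin,fmax,nfft Filterbank settings (see
#'   [mel_filterbank()]).
#' @return Frames-by-`n_coeffs` MFCC matrix.
#' @export
mfcc <- function(signal, frame_ms = 20, hop_ms = 10, n_filters = 26L,
                 fmin = 30, fmax = 500, nfft = 256L, n_coeffs = 13L,
                 drop_c0 = FALSE) {
  bank <- mel_filterbank(signal$rate, n_filters, fmin, fmax, nfft)
  mfcc_frames(frame_signal(signal, frame_ms, hop_ms), bank, n_coeffs,
              drop_c0 = drop_c0)
}

#' First- and second-order delta features
#'
#' Regression deltas over a ±`width` frame window with edge replication:
#' `d_t = sum_n n (c_{t+n} - c_{t-n}) / (2 sum_n n^2)`; delta-delta is the
#' delta of the delta. Returns `[MFCC, delta, delta-delta]` column-bound
#' (39 columns for 13-column input). A single frame yields zero deltas.
#'
#' @param m Frames-by-coefficients matrix.
#' @param width Regression half-width in frames (default 2).
#' @return Frames-by-`3 * ncol(m)` matrix.
#' @export
delta_features <- function(m, width = 2L) {
  m <- as.matrix(m)
  d1 <- delta_of(m, width)
  d2 <- delta_of(d1, width)
  cbind(m, d1, d2)
}

delta_of <- function(m, width) {
  n <- nrow(m)
  if (n <= 1L) return(matrix(0, n, ncol(m)))
  denom <- 2 * sum((seq_len(width))^2)
  idx <- function(i) pmin(pmax(i, 1L), n)
  out <- matrix(0, n, ncol(m))
  for (w in seq_len(width)) {
    out <- out + w * (m[idx(seq_len(n) + w), , drop = FALSE] -
                        m[idx(seq_len(n) - w), , drop = FALSE])
  }
  out / denom
}

#' Aggregate frame features over a fragment
#'
#' Per-dimension mean and standard deviation over frames, giving a fixed
#' 2-x-dimension vector per fragment regardless of its length (78 for the
#' default 39-dimension frame features). Single-frame fragments get zero
#' standard deviations. Invariant to frame order.
#'
#' @param feat Frames-by-dimensions matrix.
#' @return Named numeric vector `c(mean_*, sd_*)`.
#' @export
aggregate_fragment <- function(feat) {
  feat <- as.matrix(feat)
  stopifnot(nrow(feat) >= 1L)
  mu <- colMeans(feat)
  sd_ <- if (nrow(feat) > 1L) apply(feat, 2L, stats::sd) else numeric(ncol(feat))
  nm <- colnames(feat)
  if (is.null(nm)) nm <- paste0("d", seq_len(ncol(feat)))
  stats::setNames(c(mu, sd_), c(paste0("mean_", nm), paste0("sd_", nm)))
}

#' Fit PCA on training rows, project both sets, z-score normalize
#'
#' The projection and all normalization statistics come from the training
#' rows only (no test-set leakage). Components are kept up to the smallest
#' count whose cumulative explained variance reaches `retained_variance`
#' (or exactly `n_components` when given).
#'
#' @param train_X,test_X Numeric matrices with matching columns (`test_X`
#'   may be `NULL`).
#' @param retained_variance Fraction of variance to retain, in (0, 1].
#' @param n_components Optional fixed component count overriding
#'   `retained_variance`.
#' @return List with `train`, `test` (projected, z-scored), `rotation`,
#'   `center`, `n_components`, `scale_mu`, `scale_sd`.
#' @export
pca_fit_transform <- function(train_X, test_X = NULL, retained_variance = 0.95,
                              n_components = NULL) {
  train_X <- as.matrix(train_X)
  if (nrow(train_X) < 2L) stop("need >= 2 training rows", call. = FALSE)
  if (is.null(n_components) &&
      (retained_variance <= 0 || retained_variance > 1)) {
    stop("retained_variance must be in (0, 1]", call. = FALSE)
  }
  pc <- stats::prcomp(train_X, center = TRUE, scale. = FALSE)
  if (is.null(n_components)) {
    v <- pc$sdev^2
    cum <- cumsum(v) / sum(v)
    k <- if (retained_variance >= 1) {
      min(nrow(train_X) - 1L, ncol(train_X), length(v))
    } else {
      which(cum >= retained_variance - 1e-12)[1L]
    }
  } else {
    k <- min(n_components, ncol(pc$rotation))
  }
  k <- max(1L, k)
  rot <- pc$rotation[, seq_len(k), drop = FALSE]
  tr <- pc$x[, seq_len(k), drop = FALSE]
  mu <- colMeans(tr)
  sd_ <- apply(tr, 2L, stats::sd)
  sd_[!is.finite(sd_) | sd_ < 1e-12] <- 1
  zs <- function(m) sweep(sweep(m, 2L, mu), 2L, sd_, `/`)
  te <- NULL
  if (!is.null(test_X)) {
    te <- zs(sweep(as.matrix(test_X), 2L, pc$center) %*% rot)
  }
  list(train = zs(tr), test = te, rotation = rot, center = pc$center,
       n_components = k, scale_mu = mu, scale_sd = sd_)
}

#' 39-dimension fragment features
#'
#' The full per-fragment feature path: MFCC (13) + delta + delta-delta (39
#' per frame), aggregated to a 78-dimension mean/sd vector.
#'
#' @param fragment A `cycle_fragment` or [pcg_signal].
#' @param ... Passed to [mfcc()].
#' @return Named numeric vector of length 78.
#' @export
fragment_features <- function(fragment, ...) {
  sig <- if (inherits(fragment, "cycle_fragment")) fragment_signal(fragment)
         else fragment
  aggregate_fragment(delta_features(mfcc(sig, ...)))
}
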