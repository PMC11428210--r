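# Independent brute-force oracles, kept deliberately naive (explicit loops,
# textbook formulas) so they share no code with the implementation they check.

# y[n] = sum_{k=1..K} f[k] * x[n - (K - k) d], zero outside the signal
oracle_dilated_conv <- function(x, f, d) {
  n <- length(x)
  K <- length(f)
  y <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0
    for (k in seq_len(K)) {
      j <- i - (K - k) * d
      if (j >= 1 && j <= n) acc <- acc + f[k] * x[j]
    }
    y[i] <- acc
  }
  y
}

# literal scalar transcription of the LSTM gate equations
oracle_lstm_step <- function(x_t, h_prev, C_prev, W_i, W_f, W_o, W_C,
                             b_i, b_f, b_o, b_C) {
  hx <- c(h_prev, x_t)
  H <- length(h_prev)
  sig <- function(z) 1 / (1 + exp(-z))
  h <- numeric(H); C <- numeric(H)
  for (u in seq_len(H)) {
    i_u <- sig(sum(W_i[u, ] * hx) + b_i[u])
    f_u <- sig(sum(W_f[u, ] * hx) + b_f[u])
    o_u <- sig(sum(W_o[u, ] * hx) + b_o[u])
    g_u <- tanh(sum(W_C[u, ] * hx) + b_C[u])
    C[u] <- f_u * C_prev[u] + i_u * g_u
    h[u] <- o_u * tanh(C[u])
  }
  list(h = h, C = C)
}

# naive MFCC of one frame: loop DFT, loop mel filters, loop DCT-II
oracle_mfcc_frame <- function(frame, rate, n_filters = 26, fmin = 30,
                              fmax = 500, nfft = 256, n_coeffs = 13,
                              eps = 1e-10) {
  padded <- c(frame, numeric(nfft - length(frame)))
  n_bins <- nfft / 2 + 1
  power <- numeric(n_bins)
  for (b in seq_len(n_bins)) {
    re <- 0; im <- 0
    for (t in seq_len(nfft)) {
      ang <- -2 * pi * (b - 1) * (t - 1) / nfft
      re <- re + padded[t] * cos(ang)
      im <- im + padded[t] * sin(ang)
    }
    power[b] <- re^2 + im^2
  }
  mel <- function(f) 2595 * log10(1 + f / 700)
  imel <- function(m) 700 * (10^(m / 2595) - 1)
  edges <- imel(seq(mel(fmin), mel(fmax), length.out = n_filters + 2))
  bin_hz <- (seq_len(n_bins) - 1) * rate / nfft
  loge <- numeric(n_filters)
  for (i in seq_len(n_filters)) {
    e <- 0
    for (b in seq_len(n_bins)) {
      f <- bin_hz[b]
      w <- 0
      if (f >= edges[i] && f <= edges[i + 1]) {
        w <- (f - edges[i]) / (edges[i + 1] - edges[i])
      } else if (f > edges[i + 1] && f <= edges[i + 2]) {
        w <- (edges[i + 2] - f) / (edges[i + 2] - edges[i + 1])
      }
      e <- e + w * power[b]
    }
    loge[i] <- log(max(e, eps))
  }
  cep <- numeric(n_coeffs)
  for (k in seq_len(n_coeffs)) {
    acc <- 0
    for (m in seq_len(n_filters)) {
      acc <- acc + loge[m] * cos(pi * (k - 1) * (m - 0.5) / n_filters)
    }
    scale <- if (k == 1) sqrt(1 / n_filters) else sqrt(2 / n_filters)
    cep[k] <- scale * acc
  }
  cep
}

# literal transcription of the metric formulas, conventional and
# printed precision variants
oracle_metrics <- function(tp, fp, tn, fn, printed = FALSE) {
  acc <- (tp + tn) / (tp + fp + tn + fn)
  se <- if (tp + fn > 0) tp / (tp + fn) else 0
  p <- if (printed) {
    if (tn + fp > 0) tn / (tn + fp) else 0
  } else {
    if (tp + fp > 0) tp / (tp + fp) else 0
  }
  f1 <- if (se + p > 0) 2 * se * p / (se + p) else 0
  c(Acc = acc, Se = se, P = p, F1 = f1)
}
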