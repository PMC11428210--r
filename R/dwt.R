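# Periodized discrete wavelet transform with the Daubechies-6 (12-tap)
# filters. Only what the wavelet envelope needs: analysis to level 3 and
# reconstruction of a single detail band. The periodization convention
# matches the common one (circular extension; analysis offset L/2, synthesis
# offset L/2 - 1), which keeps ceil(N/2) coefficients per band and gives
# perfect reconstruction. Odd-length inputs are padded by repeating the last
# sample.

db6_dec_lo <- c(
  -0.0010773010853084796,  0.004777257510945511,   0.0005538422011614961,
  -0.03158203931748603,    0.027522865530305727,   0.09750160558732304,
  -0.12976686756726194,   -0.22626469396543983,    0.31525035170919763,
   0.7511339080210954,     0.49462389039845306,    0.11154074335010947)

db6_dec_hi <- rev(db6_dec_lo) * rep_len(c(-1, 1), length(db6_dec_lo))
db6_rec_lo <- rev(db6_dec_lo)
db6_rec_hi <- rev(db6_dec_hi)

# circular convolution y[n] = sum_m f[m] x[(n + off - m) mod N], n = 1..N
# (1-based; off in the 0-based convention above)
circ_filter <- function(x, f, off) {
  n <- length(x)
  acc <- numeric(n)
  idx0 <- seq.int(0L, n - 1L)
  for (m in seq_along(f)) {
    j <- (idx0 + off - (m - 1L)) %% n
    acc <- acc + f[m] * x[j + 1L]
  }
  acc
}

dwt_step <- function(x) {
  if (length(x) %% 2L == 1L) x <- c(x, x[length(x)])
  L <- length(db6_dec_lo)
  lo <- circ_filter(x, db6_dec_lo, L %/% 2L)
  hi <- circ_filter(x, db6_dec_hi, L %/% 2L)
  keep <- seq.int(1L, length(x), by = 2L)  # even 0-based output positions
  list(a = lo[keep], d = hi[keep])
}

idwt_step <- function(a, d, n_out = 2L * length(a)) {
  n <- 2L * length(a)
  up_a <- numeric(n); up_a[seq.int(1L, n, by = 2L)] <- a
  up_d <- numeric(n); up_d[seq.int(1L, n, by = 2L)] <- d
  L <- length(db6_rec_lo)
  x <- circ_filter(up_a, db6_rec_lo, L %/% 2L - 1L) +
       circ_filter(up_d, db6_rec_hi, L %/% 2L - 1L)
  x[seq_len(n_out)]
}

# analysis to `level`, returning approximation and the detail bands d1..dlevel
# plus the band lengths needed to invert
dwt_multilevel <- function(x, level = 3L) {
  details <- vector("list", level)
  lens <- integer(level)
  a <- x
  for (l in seq_len(level)) {
    lens[l] <- length(a)
    s <- dwt_step(a)
    a <- s$a
    details[[l]] <- s$d
  }
  list(a = a, d = details, lens = lens)
}

# reconstruct the signal keeping only detail band `keep_level`
dwt_reconstruct_detail <- function(decomp, keep_level) {
  level <- length(decomp$d)
  a <- numeric(length(decomp$a))
  for (l in rev(seq_len(level))) {
    d <- if (l == keep_level) decomp$d[[l]] else numeric(length(decomp$d[[l]]))
    a <- idwt_step(a, d, decomp$lens[l])
  }
  a
}
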