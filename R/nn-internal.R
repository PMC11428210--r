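# Internal vectorized neural-network primitives for the TBLSTM segmenter.
# Minibatches are 3-D arrays with dims (time, batch, channel); all layers
# provide a hand-derived backward pass. No external autodiff is used.

mat3 <- function(A) matrix(A, nrow = dim(A)[1] * dim(A)[2])
unmat3 <- function(M, T_, B) array(M, dim = c(T_, B, ncol(M)))

# shift along time by s frames into the future (zero-pad the past)
shift3 <- function(A, s) {
  if (s == 0L) return(A)
  d <- dim(A)
  out <- array(0, d)
  if (s < d[1]) out[(s + 1L):d[1], , ] <- A[1L:(d[1] - s), , ]
  out
}

sigmoid <- function(x) 1 / (1 + exp(-x))

## ---- causal / dilated causal convolution ------------------------------

# W: array (K, Cin, Cout); b: length Cout; dilation d >= 1.
# y_n = b + sum_k x_{n-(K-k)d} %*% W[k,,]
conv3 <- function(A, W, b, d) {
  K <- dim(W)[1]; T_ <- dim(A)[1]; B <- dim(A)[2]
  Cout <- dim(W)[3]
  Y <- matrix(rep(b, each = T_ * B), nrow = T_ * B, ncol = Cout)
  for (k in seq_len(K)) {
    Wk <- matrix(W[k, , ], nrow = dim(W)[2])
    Y <- Y + mat3(shift3(A, (K - k) * d)) %*% Wk
  }
  unmat3(Y, T_, B)
}

conv3_bwd <- function(dY, A, W, d) {
  K <- dim(W)[1]; T_ <- dim(A)[1]; B <- dim(A)[2]
  dYm <- mat3(dY)
  dW <- array(0, dim(W))
  dA <- array(0, dim(A))
  for (k in seq_len(K)) {
    s <- (K - k) * d
    Wk <- matrix(W[k, , ], nrow = dim(W)[2])
    dW[k, , ] <- crossprod(mat3(shift3(A, s)), dYm)
    dAk <- unmat3(tcrossprod(dYm, Wk), T_, B)
    if (s == 0L) {
      dA <- dA + dAk
    } else if (s < T_) {
      dA[1L:(T_ - s), , ] <- dA[1L:(T_ - s), , ] + dAk[(s + 1L):T_, , ]
    }
  }
  list(dA = dA, dW = dW, db = colSums(dYm))
}

## ---- max pooling (window 2, stride 2) ---------------------------------

pool2_fwd <- function(A) {
  T_ <- dim(A)[1]; T2 <- T_ %/% 2L
  i1 <- seq.int(1L, 2L * T2, by = 2L)
  A1 <- A[i1, , , drop = FALSE]
  A2 <- A[i1 + 1L, , , drop = FALSE]
  m <- A1 >= A2
  list(out = ifelse(m, A1, A2), mask = m)
}

pool2_bwd <- function(dOut, mask, T_in, B, C) {
  dA <- array(0, c(T_in, B, C))
  T2 <- dim(dOut)[1]
  i1 <- seq.int(1L, 2L * T2, by = 2L)
  dA[i1, , ] <- dOut * mask
  dA[i1 + 1L, , ] <- dOut * !mask
  dA
}

## ---- linear interpolation upsampling ----------------------------------

# dense (T_out x L) matrix with endpoint-aligned linear interpolation
interp_matrix <- function(T_out, L) {
  U <- matrix(0, T_out, L)
  if (L == 1L) { U[, 1L] <- 1; return(U) }
  p <- if (T_out == 1L) 1 else (seq_len(T_out) - 1) * (L - 1) / (T_out - 1) + 1
  i0 <- pmin(floor(p), L - 1L)
  w <- p - i0
  U[cbind(seq_len(T_out), i0)] <- U[cbind(seq_len(T_out), i0)] + (1 - w)
  U[cbind(seq_len(T_out), i0 + 1L)] <- U[cbind(seq_len(T_out), i0 + 1L)] + w
  U
}

upsample_fwd <- function(A, U) {
  d <- dim(A)
  Y <- U %*% matrix(A, nrow = d[1])
  array(Y, c(nrow(U), d[2], d[3]))
}

upsample_bwd <- function(dY, U, B, C) {
  dA <- crossprod(U, matrix(dY, nrow = nrow(U)))
  array(dA, c(ncol(U), B, C))
}

## ---- residual block ----------------------------------------------------

# params: list(dconv_W, dconv_b, conv_W, conv_b, skip_W (optional))
resblock_fwd <- function(A, p, d) {
  h1 <- conv3(A, p$dconv_W, p$dconv_b, d)
  a1 <- pmax(h1, 0)
  h2 <- conv3(a1, p$conv_W, p$conv_b, 1L)
  a2 <- pmax(h2, 0)
  skip <- if (is.null(p$skip_W)) A else {
    d0 <- dim(A)
    unmat3(mat3(A) %*% p$skip_W, d0[1], d0[2])
  }
  list(out = a2 + skip, cache = list(A = A, h1 = h1, a1 = a1, h2 = h2))
}

resblock_bwd <- function(dOut, cache, p, d) {
  da2 <- dOut * (cache$h2 > 0)
  g2 <- conv3_bwd(da2, cache$a1, p$conv_W, 1L)
  da1 <- g2$dA * (cache$h1 > 0)
  g1 <- conv3_bwd(da1, cache$A, p$dconv_W, d)
  dA <- g1$dA
  grads <- list(dconv_W = g1$dW, dconv_b = g1$db,
                conv_W = g2$dW, conv_b = g2$db)
  if (is.null(p$skip_W)) {
    dA <- dA + dOut
  } else {
    d0 <- dim(cache$A)
    grads$skip_W <- crossprod(mat3(cache$A), mat3(dOut))
    dA <- dA + unmat3(tcrossprod(mat3(dOut), p$skip_W), d0[1], d0[2])
  }
  list(dA = dA, grads = grads)
}

## ---- LSTM (combined-gate parameterization) -----------------------------

# W: (Cin + H) x 4H with gate column blocks [i | f | o | g]; b: 4H.
# Returns per-step caches needed for BPTT.
lstm_fwd <- function(X, W, b) {
  d <- dim(X); T_ <- d[1]; B <- d[2]; Cin <- d[3]
  H <- length(b) %/% 4L
  gi <- seq_len(H); gf <- gi + H; go <- gf + H; gg <- go + H
  Bb <- matrix(b, B, 4L * H, byrow = TRUE)
  I <- G <- O <- Fg <- Cc <- Tc <- Hh <- array(0, c(T_, B, H))
  h <- matrix(0, B, H); cc <- matrix(0, B, H)
  for (t in seq_len(T_)) {
    xt <- matrix(X[t, , ], nrow = B)
    z <- cbind(h, xt) %*% W + Bb
    it <- sigmoid(z[, gi, drop = FALSE])
    ft <- sigmoid(z[, gf, drop = FALSE])
    ot <- sigmoid(z[, go, drop = FALSE])
    gt <- tanh(z[, gg, drop = FALSE])
    cc <- ft * cc + it * gt
    tc <- tanh(cc)
    h <- ot * tc
    I[t, , ] <- it; Fg[t, , ] <- ft; O[t, , ] <- ot; G[t, , ] <- gt
    Cc[t, , ] <- cc; Tc[t, , ] <- tc; Hh[t, , ] <- h
  }
  list(H = Hh, cache = list(I = I, Fg = Fg, O = O, G = G, Cc = Cc, Tc = Tc,
                            X = X, Hh = Hh))
}

lstm_bwd <- function(dH, cache, W) {
  X <- cache$X
  d <- dim(X); T_ <- d[1]; B <- d[2]; Cin <- d[3]
  H <- dim(cache$I)[3]
  dW <- matrix(0, nrow(W), ncol(W)); db <- numeric(4L * H)
  dX <- array(0, d)
  dh_next <- matrix(0, B, H); dc_next <- matrix(0, B, H)
  for (t in rev(seq_len(T_))) {
    it <- matrix(cache$I[t, , ], B); ft <- matrix(cache$Fg[t, , ], B)
    ot <- matrix(cache$O[t, , ], B); gt <- matrix(cache$G[t, , ], B)
    tc <- matrix(cache$Tc[t, , ], B)
    c_prev <- if (t > 1L) matrix(cache$Cc[t - 1L, , ], B) else matrix(0, B, H)
    h_prev <- if (t > 1L) matrix(cache$Hh[t - 1L, , ], B) else matrix(0, B, H)
    xt <- matrix(X[t, , ], B)

    dh <- matrix(dH[t, , ], B) + dh_next
    do_ <- dh * tc
    dc <- dc_next + dh * ot * (1 - tc^2)
    di <- dc * gt
    dg <- dc * it
    df <- dc * c_prev
    dc_next <- dc * ft
    dz <- cbind(di * it * (1 - it), df * ft * (1 - ft),
                do_ * ot * (1 - ot), dg * (1 - gt^2))
    inp <- cbind(h_prev, xt)
    dW <- dW + crossprod(inp, dz)
    db <- db + colSums(dz)
    dinp <- tcrossprod(dz, W)
    dh_next <- dinp[, seq_len(H), drop = FALSE]
    dX[t, , ] <- dinp[, H + seq_len(Cin), drop = FALSE]
  }
  list(dX = dX, dW = dW, db = db)
}

rev3 <- function(A) A[rev(seq_len(dim(A)[1])), , , drop = FALSE]
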