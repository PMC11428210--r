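# The TBLSTM segmenter: a serial pyramid of five dilated-causal-convolution
# residual blocks with max pooling between blocks, per-scale outputs
# interpolated back to the input frame count and concatenated (multi-scale
# fusion), a bidirectional LSTM, dropout, and a dense softmax frame
# classifier over the four cardiac states.

#' TBLSTM model configuration
#'
#' Defaults follow the reference TBLSTM training recipe (dilations 2, 4, 8, 16, 16;
#' Adam with learning rate 0.001; batch size 32; 90 epochs; four output
#' states) with the remaining architecture constants as package choices:
#' kernel size 3, 32 channels per block, 64 LSTM units per direction,
#' dropout 0.25 after the Bi-LSTM.
#'
#' @param dilations Integer vector of per-block dilation rates.
#' @param kernel_size Convolution kernel length K for both conv layers.
#' @param channels Channels per residual block.
#' @param lstm_hidden LSTM units per direction.
#' @param bidirectional Use a Bi-LSTM (`TRUE`) or a forward LSTM only.
#' @param dropout_rate Dropout probability after the (Bi-)LSTM.
#' @param n_classes Number of output states (4).
#' @param lr Adam learning rate.
#' @param batch_size Minibatch size.
#' @param epochs Training epochs.
#' @param seed RNG seed funnelling all initialization/shuffling/dropout.
#' @param n_input Input feature channels (4 envelopes).
#' @param fusion `"concat"` (default) or `"sum"` of the upsampled scales.
#' @param class_weights `NULL` (unweighted loss) or `"inverse"` for
#'   inverse-frequency class weights.
#' @return A list of class `tblstm_config`.
#' @export
tblstm_config <- function(dilations = c(2L, 4L, 8L, 16L, 16L),
                          kernel_size = 3L, channels = 32L, lstm_hidden = 64L,
                          bidirectional = TRUE, dropout_rate = 0.25,
                          n_classes = 4L, lr = 0.001, batch_size = 32L,
                          epochs = 90L, seed = 1L, n_input = 4L,
                          fusion = c("concat", "sum"), class_weights = NULL) {
  fusion <- match.arg(fusion)
  stopifnot(all(dilations >= 1L), kernel_size >= 1L, channels >= 1L,
            lstm_hidden >= 1L, dropout_rate >= 0, dropout_rate < 1,
            n_classes >= 2L, lr > 0, batch_size >= 1L, epochs >= 1L)
  structure(list(dilations = as.integer(dilations),
                 kernel_size = as.integer(kernel_size),
                 channels = as.integer(channels),
                 lstm_hidden = as.integer(lstm_hidden),
                 bidirectional = isTRUE(bidirectional),
                 dropout_rate = dropout_rate, n_classes = as.integer(n_classes),
                 lr = lr, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = as.integer(seed),
                 n_input = as.integer(n_input), fusion = fusion,
                 class_weights = class_weights),
            class = "tblstm_config")
}

runif_init <- function(dims, fan_in) {
  s <- sqrt(6 / fan_in)
  array(stats::runif(prod(dims), -s, s), dims)
}

tblstm_init <- function(config) {
  set.seed(config$seed)
  K <- config$kernel_size; C <- config$channels; H <- config$lstm_hidden
  nb <- length(config$dilations)
  p <- list()
  c_in <- config$n_input
  for (i in seq_len(nb)) {
    p[[paste0("b", i, "_dconv_W")]] <- runif_init(c(K, c_in, C), K * c_in)
    p[[paste0("b", i, "_dconv_b")]] <- numeric(C)
    p[[paste0("b", i, "_conv_W")]] <- runif_init(c(K, C, C), K * C)
    p[[paste0("b", i, "_conv_b")]] <- numeric(C)
    if (c_in != C) {
      p[[paste0("b", i, "_skip_W")]] <- runif_init(c(c_in, C), c_in)
    }
    c_in <- C
  }
  fused <- if (config$fusion == "concat") nb * C else C
  dirs <- if (config$bidirectional) c("fw", "bw") else "fw"
  for (dr in dirs) {
    p[[paste0("lstm_", dr, "_W")]] <- runif_init(c(fused + H, 4L * H), fused + H)
    b <- numeric(4L * H)
    b[H + seq_len(H)] <- 1  # forget-gate bias init
    p[[paste0("lstm_", dr, "_b")]] <- b
  }
  d_in <- if (config$bidirectional) 2L * H else H
  p$dense_W <- runif_init(c(d_in, config$n_classes), d_in)
  p$dense_b <- numeric(config$n_classes)
  p
}

## ---- full network forward / backward -----------------------------------

tcn_fwd <- function(A, params, config) {
  T_ <- dim(A)[1]; B <- dim(A)[2]
  nb <- length(config$dilations)
  caches <- vector("list", nb)
  Us <- vector("list", nb)
  ups <- vector("list", nb)
  cur <- A
  for (i in seq_len(nb)) {
    bp <- list(dconv_W = params[[paste0("b", i, "_dconv_W")]],
               dconv_b = params[[paste0("b", i, "_dconv_b")]],
               conv_W = params[[paste0("b", i, "_conv_W")]],
               conv_b = params[[paste0("b", i, "_conv_b")]],
               skip_W = params[[paste0("b", i, "_skip_W")]])
    rb <- resblock_fwd(cur, bp, config$dilations[i])
    Us[[i]] <- interp_matrix(T_, dim(rb$out)[1])
    ups[[i]] <- upsample_fwd(rb$out, Us[[i]])
    pl <- pool2_fwd(rb$out)
    caches[[i]] <- list(rb = rb$cache, pool_mask = pl$mask,
                        out_len = dim(rb$out)[1])
    cur <- pl$out
  }
  fused <- if (config$fusion == "concat") {
    array(unlist(ups), c(T_, B, nb * config$channels))
  } else {
    Reduce(`+`, ups)
  }
  list(fused = fused, caches = caches, Us = Us)
}

tcn_bwd <- function(dFused, tcn_cache, params, config) {
  nb <- length(config$dilations)
  C <- config$channels
  T_ <- dim(dFused)[1]; B <- dim(dFused)[2]
  grads <- list()
  dcur <- NULL  # gradient flowing into the pooled stream, from deepest block back
  for (i in rev(seq_len(nb))) {
    ci <- tcn_cache$caches[[i]]
    dUp <- if (config$fusion == "concat") {
      dFused[, , (i - 1L) * C + seq_len(C), drop = FALSE]
    } else {
      dFused
    }
    dOut <- upsample_bwd(dUp, tcn_cache$Us[[i]], B, C)
    if (!is.null(dcur)) {
      dOut <- dOut + pool2_bwd(dcur, ci$pool_mask, ci$out_len, B, C)
    }
    bp <- list(dconv_W = params[[paste0("b", i, "_dconv_W")]],
               dconv_b = params[[paste0("b", i, "_dconv_b")]],
               conv_W = params[[paste0("b", i, "_conv_W")]],
               conv_b = params[[paste0("b", i, "_conv_b")]],
               skip_W = params[[paste0("b", i, "_skip_W")]])
    rbw <- resblock_bwd(dOut, ci$rb, bp, config$dilations[i])
    for (nm in names(rbw$grads)) {
      grads[[paste0("b", i, "_", nm)]] <- rbw$grads[[nm]]
    }
    dcur <- rbw$dA
  }
  grads
}

net_fwd <- function(A, params, config, train = FALSE) {
  T_ <- dim(A)[1]; B <- dim(A)[2]
  if (T_ < 2L^length(config$dilations)) {
    stop(sprintf("input too short: need at least %d frames, got %d",
                 2L^length(config$dilations), T_), call. = FALSE)
  }
  tcn <- tcn_fwd(A, params, config)
  fw <- lstm_fwd(tcn$fused, params$lstm_fw_W, params$lstm_fw_b)
  if (config$bidirectional) {
    bw <- lstm_fwd(rev3(tcn$fused), params$lstm_bw_W, params$lstm_bw_b)
    Hcat <- array(c(fw$H, rev3(bw$H)), c(T_, B, 2L * config$lstm_hidden))
  } else {
    bw <- NULL
    Hcat <- fw$H
  }
  drop_mask <- NULL
  Hd <- Hcat
  if (train && config$dropout_rate > 0) {
    keep <- 1 - config$dropout_rate
    drop_mask <- array(stats::rbinom(length(Hcat), 1L, keep) / keep, dim(Hcat))
    Hd <- Hcat * drop_mask
  }
  logits <- mat3(Hd) %*% params$dense_W +
    matrix(params$dense_b, T_ * B, config$n_classes, byrow = TRUE)
  mx <- apply(logits, 1L, max)
  ex <- exp(logits - mx)
  probs <- ex / rowSums(ex)
  list(probs = probs, tcn = tcn, fw = fw, bw = bw, Hd = Hd,
       drop_mask = drop_mask, T_ = T_, B = B)
}

net_bwd <- function(fwd, labels_vec, params, config, weights = NULL) {
  T_ <- fwd$T_; B <- fwd$B; H <- config$lstm_hidden
  n <- T_ * B
  onehot <- matrix(0, n, config$n_classes)
  onehot[cbind(seq_len(n), labels_vec + 1L)] <- 1
  w <- if (is.null(weights)) rep(1, n) else weights[labels_vec + 1L]
  dlogits <- (fwd$probs - onehot) * (w / sum(w))
  grads <- list(dense_W = crossprod(mat3(fwd$Hd), dlogits),
                dense_b = colSums(dlogits))
  dHd <- unmat3(tcrossprod(dlogits, params$dense_W), T_, B)
  if (!is.null(fwd$drop_mask)) dHd <- dHd * fwd$drop_mask
  if (config$bidirectional) {
    dHf <- dHd[, , seq_len(H), drop = FALSE]
    dHb <- dHd[, , H + seq_len(H), drop = FALSE]
    gf <- lstm_bwd(dHf, fwd$fw$cache, params$lstm_fw_W)
    gb <- lstm_bwd(rev3(dHb), fwd$bw$cache, params$lstm_bw_W)
    grads$lstm_fw_W <- gf$dW; grads$lstm_fw_b <- gf$db
    grads$lstm_bw_W <- gb$dW; grads$lstm_bw_b <- gb$db
    dFused <- gf$dX + rev3(gb$dX)
  } else {
    gf <- lstm_bwd(dHd, fwd$fw$cache, params$lstm_fw_W)
    grads$lstm_fw_W <- gf$dW; grads$lstm_fw_b <- gf$db
    dFused <- gf$dX
  }
  c(grads, tcn_bwd(dFused, fwd$tcn, params, config))
}

ce_loss <- function(probs, labels_vec, weights = NULL) {
  n <- nrow(probs)
  p <- probs[cbind(seq_len(n), labels_vec + 1L)]
  w <- if (is.null(weights)) rep(1, n) else weights[labels_vec + 1L]
  sum(-log(pmax(p, 1e-12)) * w) / sum(w)
}

## ---- Adam --------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) array(0, dim(p) %||% length(p))),
       v = lapply(params, function(p) array(0, dim(p) %||% length(p))),
       t = 0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adam_update <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

## ---- training ----------------------------------------------------------

features_values <- function(f) {
  if (inherits(f, "pcg_features")) f$values else as.matrix(f)
}

stack_batch <- function(feats, idx) {
  T_ <- nrow(feats[[idx[1]]])
  C <- ncol(feats[[idx[1]]])
  A <- array(0, c(T_, length(idx), C))
  for (j in seq_along(idx)) A[, j, ] <- feats[[idx[j]]]
  A
}

#' Train the TBLSTM segmenter
#'
#' Minimizes per-frame cross-entropy with Adam. All randomness
#' (initialization, epoch shuffling, dropout) is funnelled through
#' `config$seed`, so two runs with the same seed and data are identical.
#' Records are grouped by frame count so each minibatch is a dense
#' (time, batch, channel) array.
#'
#' @param features List of `pcg_features` (or frames-by-channels matrices).
#' @param labels List of [state_sequence] vectors (codes 0..3), one per
#'   record, same frame count as its features.
#' @param config A [tblstm_config].
#' @param verbose Print per-epoch loss.
#' @return A `tblstm_model`: list with `params`, `config`, `loss_curve`.
#' @export
train_segmenter <- function(features, labels, config = tblstm_config(),
                            verbose = FALSE) {
  stopifnot(length(features) == length(labels), length(features) >= 1L)
  feats <- lapply(features, features_values)
  labs <- lapply(labels, function(l) {
    l <- as.integer(l)
    if (length(l) && (min(l) < 0L || max(l) > 3L)) {
      stop("labels outside {0,1,2,3}", call. = FALSE)
    }
    l
  })
  for (i in seq_along(feats)) {
    if (nrow(feats[[i]]) != length(labs[[i]])) {
      stop("record ", i, ": feature frames != label frames", call. = FALSE)
    }
  }
  set.seed(config$seed)
  params <- tblstm_init(config)
  state <- adam_init(params)
  weights <- NULL
  if (identical(config$class_weights, "inverse")) {
    cnt <- tabulate(unlist(labs) + 1L, nbins = config$n_classes)
    weights <- sum(cnt) / pmax(cnt, 1) / config$n_classes
  }
  lens <- vapply(feats, nrow, 0L)
  loss_curve <- numeric(config$epochs)
  for (ep in seq_len(config$epochs)) {
    ord <- sample(seq_along(feats))
    batches <- list()
    for (L in unique(lens[ord])) {
      same <- ord[lens[ord] == L]
      batches <- c(batches, split(same, ceiling(seq_along(same) /
                                                  config$batch_size)))
    }
    ep_loss <- 0; ep_n <- 0
    for (bi in batches) {
      A <- stack_batch(feats, bi)
      # labels stacked to match mat3 layout: time fastest, then batch
      yv <- as.integer(unlist(labs[bi]))
      fwd <- net_fwd(A, params, config, train = TRUE)
      loss <- ce_loss(fwd$probs, yv, weights)
      if (!is.finite(loss)) {
        stop("training diverged (non-finite loss) at epoch ", ep, call. = FALSE)
      }
      grads <- net_bwd(fwd, yv, params, config, weights)
      upd <- adam_update(params, grads, state, config$lr)
      params <- upd$params; state <- upd$state
      ep_loss <- ep_loss + loss * length(yv); ep_n <- ep_n + length(yv)
    }
    loss_curve[ep] <- ep_loss / ep_n
    if (verbose) message(sprintf("epoch %3d  loss %.5f", ep, loss_curve[ep]))
  }
  structure(list(params = params, config = config, loss_curve = loss_curve,
                 trained = TRUE),
            class = "tblstm_model")
}

#' @export
print.tblstm_model <- function(x, ...) {
  cat(sprintf(
    "<tblstm_model> %d blocks (dilations %s), %s, %d channels, %d LSTM units%s\n",
    length(x$config$dilations), paste(x$config$dilations, collapse = ","),
    if (x$config$bidirectional) "Bi-LSTM" else "LSTM",
    x$config$channels, x$config$lstm_hidden,
    if (isTRUE(x$trained)) sprintf(", trained (final loss %.4f)",
                                   x$loss_curve[length(x$loss_curve)]) else ""))
  invisible(x)
}

#' Frame-state posteriors for a signal
#'
#' Runs envelopes -> multi-scale TCN -> (Bi-)LSTM -> dense -> softmax with
#' dropout disabled. Accepts a pre-processed [pcg_signal] or an existing
#' `pcg_features` matrix.
#'
#' @param model A trained `tblstm_model`.
#' @param signal A [pcg_signal] or `pcg_features`.
#' @return A `frame_posterior`: frames-by-4 probability matrix (rows sum to
#'   1) with a `frame_rate` attribute.
#' @export
predict_states <- function(model, signal) {
  if (!inherits(model, "tblstm_model") || !isTRUE(model$trained)) {
    stop("`model` must be a trained tblstm_model", call. = FALSE)
  }
  if (inherits(signal, "pcg_signal")) {
    feats <- build_feature_matrix(signal)
  } else if (inherits(signal, "pcg_features")) {
    feats <- signal
  } else {
    stop("`signal` must be a pcg_signal or pcg_features", call. = FALSE)
  }
  A <- array(feats$values, c(nrow(feats$values), 1L, ncol(feats$values)))
  fwd <- net_fwd(A, model$params, model$config, train = FALSE)
  structure(fwd$probs, frame_rate = feats$frame_rate,
            class = "frame_posterior")
}

## ---- public layer-level operations -------------------------------------

#' Causal convolution of a sequence
#'
#' `y[n] = sum_k f[k] * x[n - K + k]` with implicit left zero-padding of
#' `K - 1`, so the output has the input's length and `y[n]` depends only on
#' past and present samples.
#'
#' @param x Numeric vector.
#' @param f Kernel weights `f[1..K]`.
#' @return Numeric vector, `length(x)`.
#' @export
causal_conv <- function(x, f) dilated_causal_conv(x, f, d = 1L)

#' Dilated causal convolution of a sequence
#'
#' `y[n] = sum_k f[k] * x[n - (K - k) * d]` with left zero-padding of
#' `(K - 1) * d`; the receptive field is `(K - 1) * d + 1`.
#'
#' @param x Numeric vector.
#' @param f Kernel weights `f[1..K]`.
#' @param d Dilation rate (>= 1); `d = 1` reduces to [causal_conv()].
#' @return Numeric vector, `length(x)`.
#' @export
dilated_causal_conv <- function(x, f, d = 1L) {
  stopifnot(d >= 1L, length(f) >= 1L)
  n <- length(x)
  K <- length(f)
  y <- numeric(n)
  for (k in seq_len(K)) {
    s <- (K - k) * d
    if (s == 0L) {
      y <- y + f[k] * x
    } else if (s < n) {
      y[(s + 1L):n] <- y[(s + 1L):n] + f[k] * x[1L:(n - s)]
    }
  }
  y
}

#' Apply one residual block to a frame matrix
#'
#' Path: dilated causal conv -> ReLU -> causal conv -> ReLU; output is
#' `path(x) + skip(x)` with an identity skip (or a 1x1 projection when the
#' channel count changes).
#'
#' @param x Frames-by-channels numeric matrix.
#' @param params List with `dconv_W` (K x Cin x C array), `dconv_b`,
#'   `conv_W` (K x C x C), `conv_b`, optional `skip_W` (Cin x C).
#' @param dilation Dilation rate of the first conv.
#' @return Frames-by-C matrix, same frame count.
#' @export
residual_block <- function(x, params, dilation = 1L) {
  x <- as.matrix(x)
  if (dim(params$dconv_W)[2] != ncol(x)) {
    stop("channel mismatch between input and dconv_W", call. = FALSE)
  }
  A <- array(x, c(nrow(x), 1L, ncol(x)))
  out <- resblock_fwd(A, params, dilation)$out
  matrix(out, nrow(x))
}

#' Multi-scale TCN features
#'
#' Serial pyramid of residual blocks with max pooling (window 2, stride 2)
#' between blocks; each block's pre-pool output is linearly interpolated back
#' to the input frame count and the scales are fused channel-wise.
#'
#' @param features A `pcg_features` or frames-by-channels matrix.
#' @param config A [tblstm_config].
#' @param params Optional parameter list (defaults to a fresh initialization
#'   from `config$seed`).
#' @return Frames-by-fused-channels matrix (`length(dilations) * channels`
#'   channels under `"concat"` fusion).
#' @export
multiscale_tcn <- function(features, config = tblstm_config(), params = NULL) {
  x <- features_values(features)
  if (is.null(params)) params <- tblstm_init(config)
  A <- array(x, c(nrow(x), 1L, ncol(x)))
  if (nrow(x) < 2L^length(config$dilations)) {
    stop(sprintf("input too short: need at least %d frames",
                 2L^length(config$dilations)), call. = FALSE)
  }
  fused <- tcn_fwd(A, params, config)$fused
  matrix(fused, nrow(x))
}

#' One LSTM step
#'
#' Gate equations: `i = sigma(W_i [h, x] + b_i)`, `f = sigma(W_f [h, x] + b_f)`,
#' `o = sigma(W_o [h, x] + b_o)`, `g = tanh(W_C [h, x] + b_C)`,
#' `C = f * C_prev + i * g`, `h = o * tanh(C)` (elementwise products).
#'
#' @param x_t Input vector at step t.
#' @param h_prev,C_prev Previous hidden and cell states (length H).
#' @param params List with matrices `W_i`, `W_f`, `W_o`, `W_C` (H x (H + n_in),
#'   acting on `c(h_prev, x_t)`) and bias vectors `b_i`, `b_f`, `b_o`, `b_C`.
#' @return List with `h` and `C`, each length H.
#' @export
lstm_step <- function(x_t, h_prev, C_prev, params) {
  hx <- c(h_prev, x_t)
  i <- sigmoid(as.vector(params$W_i %*% hx) + params$b_i)
  f <- sigmoid(as.vector(params$W_f %*% hx) + params$b_f)
  o <- sigmoid(as.vector(params$W_o %*% hx) + params$b_o)
  g <- tanh(as.vector(params$W_C %*% hx) + params$b_C)
  C_t <- f * C_prev + i * g
  list(h = o * tanh(C_t), C = C_t)
}

#' (Bi-)LSTM over a frame matrix
#'
#' Runs a forward pass over `t = 1..T` and (when `bidirectional`) a backward
#' pass over `t = T..1`, concatenating the two hidden sequences column-wise.
#'
#' @param x Frames-by-channels matrix.
#' @param W,b Combined-gate weights `(n_in + H) x 4H` (column blocks
#'   `[i | f | o | g]`) and bias `4H` for the forward direction.
#' @param W_bw,b_bw Weights for the backward direction (default: shared with
#'   the forward direction).
#' @param bidirectional If `FALSE`, return only the forward hidden sequence
#'   (width H instead of 2H).
#' @return Frames-by-`2H` (or `H`) matrix of hidden states.
#' @export
bilstm <- function(x, W, b, W_bw = W, b_bw = b, bidirectional = TRUE) {
  x <- as.matrix(x)
  A <- array(x, c(nrow(x), 1L, ncol(x)))
  H <- length(b) %/% 4L
  fw <- lstm_fwd(A, W, b)
  if (!bidirectional) return(matrix(fw$H, nrow(x)))
  bw <- lstm_fwd(rev3(A), W_bw, b_bw)
  cbind(matrix(fw$H, nrow(x)), matrix(rev3(bw$H), nrow(x)))
}
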