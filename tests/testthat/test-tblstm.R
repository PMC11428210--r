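test_that("causal convolutions reproduce worked examples and the brute-force oracle", {
  expect_equal(causal_conv(c(1, 2, 3, 4), c(1, 1)), c(1, 3, 5, 7))
  expect_equal(dilated_causal_conv(c(1, 2, 3, 4), c(1, 1), d = 2),
               c(1, 2, 4, 6))
  expect_equal(causal_conv(c(5, -2, 7), 1), c(5, -2, 7))  # K = 1 identity

  set.seed(21)
  for (rep in 1:100) {
    n <- sample(5:40, 1)
    K <- sample(1:4, 1)
    d <- sample(c(1, 2, 4, 8), 1)
    x <- stats::rnorm(n)
    f <- stats::rnorm(K)
    expect_equal(dilated_causal_conv(x, f, d), oracle_dilated_conv(x, f, d),
                 tolerance = 1e-6)
  }
  # d = 1 reduces exactly to the causal form
  x <- stats::rnorm(30); f <- stats::rnorm(3)
  expect_identical(dilated_causal_conv(x, f, 1L), causal_conv(x, f))
})

test_that("convolution output is causal: perturbations propagate only forward", {
  set.seed(22)
  x <- stats::rnorm(50)
  f <- stats::rnorm(3)
  for (d in c(1, 4)) {
    y0 <- dilated_causal_conv(x, f, d)
    j <- 20
    x2 <- x; x2[j] <- x2[j] + 1
    y1 <- dilated_causal_conv(x2, f, d)
    expect_equal(y1[1:(j - 1)], y0[1:(j - 1)])
    expect_false(isTRUE(all.equal(y1[j:50], y0[j:50])))
  }
})

test_that("receptive field equals (K-1)d+1 by perturbation probing", {
  set.seed(23)
  for (K in 2:3) {
    for (d in c(1, 2, 4, 8, 16)) {
      f <- stats::rnorm(K)
      f[abs(f) < 0.1] <- 0.5       # ensure no accidentally-zero taps
      n <- (K - 1) * d + 40
      x <- stats::rnorm(n)
      y0 <- dilated_causal_conv(x, f, d)
      probe <- n - 5
      affected <- vapply(seq_len(n), function(j) {
        x2 <- x; x2[j] <- x2[j] + 1
        !isTRUE(all.equal(dilated_causal_conv(x2, f, d)[probe],
                          y0[probe], tolerance = 1e-12))
      }, logical(1))
      span <- range(which(affected))
      expect_equal(span[2] - span[1] + 1, (K - 1) * d + 1)
      expect_equal(span[2], probe)  # no future leakage
    }
  }
})

test_that("residual block preserves length and passes input through a zeroed path", {
  set.seed(24)
  C <- 3L; K <- 3L
  x <- matrix(stats::rnorm(40 * C), 40, C)
  zero_params <- list(dconv_W = array(0, c(K, C, C)), dconv_b = numeric(C),
                      conv_W = array(0, c(K, C, C)), conv_b = numeric(C))
  expect_equal(residual_block(x, zero_params, dilation = 4L), x)

  for (d in c(1, 2, 8)) {
    p <- list(dconv_W = array(stats::rnorm(K * C * C) / 3, c(K, C, C)),
              dconv_b = stats::rnorm(C),
              conv_W = array(stats::rnorm(K * C * C) / 3, c(K, C, C)),
              conv_b = stats::rnorm(C))
    expect_equal(dim(residual_block(x, p, d)), dim(x))
  }
  expect_error(residual_block(x[, 1:2], zero_params, 1L), "mismatch")
})

test_that("gradient flows through the skip path even with zeroed conv weights", {
  env <- asNamespace("pcgseg")
  C <- 2L
  A <- array(stats::rnorm(20 * 1 * C), c(20, 1, C))
  p <- list(dconv_W = array(0, c(3, C, C)), dconv_b = numeric(C),
            conv_W = array(0, c(3, C, C)), conv_b = numeric(C),
            skip_W = NULL)
  fwd <- env$resblock_fwd(A, p, 2L)
  dOut <- array(stats::rnorm(20 * 1 * C), c(20, 1, C))
  bwd <- env$resblock_bwd(dOut, fwd$cache, p, 2L)
  expect_gt(max(abs(bwd$dA)), 0)
  # finite-difference check of the skip path
  eps <- 1e-6
  i <- 7L
  A2 <- A; A2[i, 1, 1] <- A2[i, 1, 1] + eps
  fd <- (sum(env$resblock_fwd(A2, p, 2L)$out * dOut) -
           sum(fwd$out * dOut)) / eps
  expect_equal(fd, bwd$dA[i, 1, 1], tolerance = 1e-4)
})

test_that("multi-scale fusion pools, interpolates and concatenates as specified", {
  env <- asNamespace("pcgseg")
  expect_equal(as.vector(env$pool2_fwd(array(c(3, 1, 4, 1, 5, 9),
                                             c(6, 1, 1)))$out),
               c(3, 4, 9))

  cfg <- tblstm_config(channels = 4L)
  x <- matrix(stats::rnorm(250 * 4), 250, 4)
  fused <- multiscale_tcn(x, cfg)
  expect_equal(nrow(fused), 250L)
  expect_equal(ncol(fused), 5L * 4L)  # 5 blocks x channels

  # internal pooled lengths 125, 62, 31, 15, 7
  A <- array(x, c(250, 1, 4))
  params <- pcgseg:::tblstm_init(cfg)
  tc <- env$tcn_fwd(A, params, cfg)
  pre_pool <- vapply(seq_along(tc$caches),
                     function(i) tc$caches[[i]]$out_len, 0L)
  expect_equal(pre_pool, c(250L, 125L, 62L, 31L, 15L))
  expect_equal(pre_pool %/% 2L, c(125L, 62L, 31L, 15L, 7L))  # pooled lengths

  expect_error(multiscale_tcn(x[1:20, ], cfg), "short")
})

test_that("scale fusion preserves frame count for lengths 32..4096", {
  cfg <- tblstm_config(channels = 2L, lstm_hidden = 2L)
  params <- pcgseg:::tblstm_init(cfg)
  for (n in c(32L, 33L, 100L, 251L, 1024L, 4096L)) {
    x <- matrix(stats::rnorm(n * 4), n, 4)
    expect_equal(nrow(multiscale_tcn(x, cfg, params)), n)
  }
})

test_that("TCN layer outputs at frame t ignore future frames", {
  cfg <- tiny_config()
  params <- pcgseg:::tblstm_init(cfg)
  set.seed(31)
  x <- matrix(stats::rnorm(64 * 4), 64, 4)
  base <- multiscale_tcn(x, cfg, params)
  # NOTE: pooling/interpolation mixes a frame with its window partner, so
  # causality is asserted for the conv stack at the first scale (channels
  # of block 1, which sees the raw frame grid).
  x2 <- x; x2[40, ] <- x2[40, ] + 5
  pert <- multiscale_tcn(x2, cfg, params)
  expect_equal(pert[1:38, 1:cfg$channels], base[1:38, 1:cfg$channels])
})

test_that("lstm step follows the gate equations exactly", {
  H <- 3L; n_in <- 2L
  zero <- list(W_i = matrix(0, H, H + n_in), W_f = matrix(0, H, H + n_in),
               W_o = matrix(0, H, H + n_in), W_C = matrix(0, H, H + n_in),
               b_i = numeric(H), b_f = numeric(H), b_o = numeric(H),
               b_C = numeric(H))
  C_prev <- c(1, -2, 0.5)
  st <- lstm_step(c(1, 1), numeric(H), C_prev, zero)
  expect_equal(st$C, 0.5 * C_prev)             # f = 0.5, i*g = 0
  expect_equal(st$h, 0.5 * tanh(0.5 * C_prev)) # o = 0.5

  set.seed(41)
  for (rep in 1:100) {
    W <- lapply(1:4, function(i) matrix(stats::rnorm(H * (H + n_in)), H))
    b <- lapply(1:4, function(i) stats::rnorm(H))
    x_t <- stats::rnorm(n_in); h0 <- stats::rnorm(H); C0 <- stats::rnorm(H)
    got <- lstm_step(x_t, h0, C0,
                     list(W_i = W[[1]], W_f = W[[2]], W_o = W[[3]],
                          W_C = W[[4]], b_i = b[[1]], b_f = b[[2]],
                          b_o = b[[3]], b_C = b[[4]]))
    ref <- oracle_lstm_step(x_t, h0, C0, W[[1]], W[[2]], W[[3]], W[[4]],
                            b[[1]], b[[2]], b[[3]], b[[4]])
    expect_equal(got$h, ref$h, tolerance = 1e-10)
    expect_equal(got$C, ref$C, tolerance = 1e-10)
    expect_true(all(abs(got$h) < 1))           # tanh/sigmoid bounds
  }
})

test_that("bilstm halves are time-reversed copies on palindromic input", {
  H <- 4L; C <- 3L
  set.seed(42)
  W <- matrix(stats::rnorm((C + H) * 4 * H) / 4, C + H, 4 * H)
  b <- stats::rnorm(4 * H) / 4
  half <- matrix(stats::rnorm(10 * C), 10, C)
  x <- rbind(half, half[10:1, ])  # palindrome
  out <- bilstm(x, W, b)
  expect_equal(ncol(out), 2L * H)
  fw <- out[, 1:H]; bw <- out[, H + 1:H]
  expect_equal(bw, fw[nrow(x):1, ], tolerance = 1e-10)

  single <- bilstm(matrix(stats::rnorm(C), 1, C), W, b)
  expect_equal(ncol(single), 2L * H)
  uni <- bilstm(x, W, b, bidirectional = FALSE)
  expect_equal(ncol(uni), H)
})

test_that("posteriors are proper distributions and training is deterministic", {
  recs <- lapply(1:3, function(i) clean_record(seed = i))
  prep <- prep_records(recs)
  cfg <- tiny_config(epochs = 3L)
  m1 <- train_segmenter(prep$features, prep$labels, cfg)
  m2 <- train_segmenter(prep$features, prep$labels, cfg)
  expect_equal(m1$loss_curve[length(m1$loss_curve)],
               m2$loss_curve[length(m2$loss_curve)], tolerance = 1e-6)
  expect_identical(m1$params, m2$params)

  post <- predict_states(m1, prep$features[[1]])
  expect_equal(nrow(post), 250L)
  expect_equal(rowSums(post), rep(1, 250), tolerance = 1e-6)
  expect_true(all(post >= 0 & post <= 1))
  expect_length(max.col(post), 250L)

  expect_gt(m1$loss_curve[1], m1$loss_curve[3])  # loss decreases
  expect_error(train_segmenter(prep$features,
                               lapply(prep$labels, function(l) l + 4L), cfg),
               "labels")
})

test_that("predicting with an untrained or wrong object is an error", {
  fake <- structure(list(trained = FALSE), class = "tblstm_model")
  rec <- clean_record(seed = 71)
  expect_error(predict_states(fake, rec$signal), "trained")
  expect_error(predict_states(list(), rec$signal), "trained")
})

test_that("a small model overfits a single record", {
  rec <- clean_record(seed = 5)
  prep <- prep_records(list(rec))
  cfg <- tblstm_config(channels = 16L, lstm_hidden = 32L, epochs = 90L,
                       seed = 3L, dropout_rate = 0.25)
  m <- train_segmenter(prep$features, prep$labels, cfg)
  post <- predict_states(m, prep$features[[1]])
  acc <- mean((max.col(post) - 1L) == as.integer(prep$labels[[1]]))
  expect_gt(acc, 0.98)
})

test_that("dropout is active only during training", {
  rec <- clean_record(seed = 6)
  prep <- prep_records(list(rec))
  cfg <- tiny_config(dropout_rate = 0.5, epochs = 2L)
  m <- train_segmenter(prep$features, prep$labels, cfg)
  p1 <- predict_states(m, prep$features[[1]])
  p2 <- predict_states(m, prep$features[[1]])
  expect_identical(unclass(p1), unclass(p2))  # inference deterministic
})
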