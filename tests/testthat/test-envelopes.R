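test_that("hilbert envelope matches the analytic-signal closed form on a tone", {
  s <- tone(50, dur_s = 2)
  env <- hilbert_envelope(s)
  expect_length(env, length(s$samples))
  expect_true(all(env >= 0))
  mid <- 200:3800
  expect_lt(max(abs(env[mid] - 1)), 0.02)

  expect_equal(hilbert_envelope(pcg_signal(numeric(100), 2000)), numeric(100))
})

test_that("literal hilbert mode gives |H{cos}| = |sin|", {
  n <- 2048
  t <- seq_len(n) - 1
  x <- cos(2 * pi * 32 * t / n)  # exact FFT bin -> clean Hilbert pair
  env <- hilbert_envelope(pcg_signal(x, 2000), mode = "literal")
  expect_equal(env, abs(sin(2 * pi * 32 * t / n)), tolerance = 1e-8)
})

test_that("homomorphic envelope recovers constant amplitude and tracks slow AM", {
  s <- tone(80, dur_s = 3)
  env <- homomorphic_envelope(s)
  mid <- 500:5500
  expect_lt(max(abs(env[mid] - 1)), 0.05)

  t <- (seq_len(6000) - 0.5) / 2000
  modu <- 1 + 0.5 * sin(2 * pi * 2 * t)
  am <- pcg_signal(modu * sin(2 * pi * 100 * t), 2000)
  env_am <- homomorphic_envelope(am)
  expect_gt(stats::cor(env_am[500:5500], modu[500:5500]), 0.95)

  z <- homomorphic_envelope(pcg_signal(numeric(500), 2000))
  expect_true(all(abs(env_con <- z - z[1]) < 1e-9))  # constant eps floor
})

test_that("db6 decomposition matches the frozen reference transform", {
  # fixture values computed with an independent periodized db6 DWT oracle
  x <- (1:16) / 7 + sin(0:15)
  dec <- pcgseg:::dwt_step(x)
  a_ref <- c(2.978636606914954, 3.7196122461279693, 1.4728804197333387,
             1.421336670252326, -0.29920272869916054, 1.909564626331724,
             2.933080074956148, 0.970904433195865)
  d_ref <- c(0.4423918864611226, -0.14980469847092534, -0.10659232879302993,
             0.21416308656390357, -0.07572372904630943, 0.07169861458519816,
             1.5330728897840253, -0.8447566325498662)
  expect_equal(dec$a, a_ref, tolerance = 1e-12)
  expect_equal(dec$d, d_ref, tolerance = 1e-12)
  expect_equal(pcgseg:::idwt_step(dec$a, dec$d), x, tolerance = 1e-12)
})

test_that("wavelet envelope isolates the level-3 detail band", {
  expect_equal(wavelet_envelope(pcg_signal(numeric(2000), 2000)),
               numeric(2000))

  # white noise: the reconstructed detail-3 signal concentrates in
  # rate/16..rate/8 (125-250 Hz at 2 kHz)
  set.seed(11)
  s <- pcg_signal(stats::rnorm(4096), 2000)
  env <- wavelet_envelope(s)
  expect_length(env, 4096)
  dec <- pcgseg:::dwt_multilevel(s$samples, 3L)
  d3 <- pcgseg:::dwt_reconstruct_detail(dec, 3L)
  spec <- Mod(stats::fft(d3))^2
  freqs <- (seq_along(d3) - 1) / length(d3) * 2000
  half <- freqs <= 1000
  in_band <- half & freqs >= 125 & freqs <= 250
  expect_gt(sum(spec[in_band]) / sum(spec[half]), 0.5)

  # out-of-band tone (40 Hz) is far weaker than an in-band tone (180 Hz)
  rms <- function(v) sqrt(mean(v^2))
  e40 <- rms(wavelet_envelope(tone(40, 2)))
  e180 <- rms(wavelet_envelope(tone(180, 2)))
  expect_lt(e40, 0.2 * e180)

  expect_error(wavelet_envelope(pcg_signal(numeric(20), 2000)), "short")
  expect_length(wavelet_envelope(s, mode = "coefficients"), 512)
})

test_that("psd envelope window count and band selectivity follow the definitions", {
  s <- pcg_signal(stats::rnorm(10000), 2000)
  expect_length(psd_envelope(s), 199)  # floor((10000-100)/50)+1

  expect_equal(psd_envelope(pcg_signal(numeric(1000), 2000)),
               rep(0, 19))

  e50 <- mean(psd_envelope(tone(50, 2), band = c(40, 60)))
  e300 <- mean(psd_envelope(tone(300, 2), band = c(40, 60)))
  expect_gt(e50, 10 * e300)

  expect_error(psd_envelope(s, band = c(900, 1100)), "Nyquist")
})

test_that("feature matrix is frame-aligned, standardized and NaN-free", {
  rec <- clean_record(seed = 2)
  f <- build_feature_matrix(rec$signal, frame_rate = 50)
  expect_equal(dim(f$values), c(250L, 4L))
  expect_false(anyNA(f$values))
  for (j in 1:4) {
    expect_lt(abs(mean(f$values[, j])), 1e-9)
    expect_equal(stats::sd(f$values[, j]), 1, tolerance = 1e-6)
  }

  # constant channel degenerates to zeros, not NaN
  z <- build_feature_matrix(pcg_signal(rep(0, 10000), 2000))
  expect_true(all(z$values == 0))
})

test_that("envelope peaks stay aligned with click times at the frame rate", {
  clicks_at <- c(1.0, 2.0, 3.0, 4.0)
  x <- numeric(10000)
  for (tc in clicks_at) {
    idx <- round(tc * 2000) + seq(-20, 20)
    x[idx] <- sin(2 * pi * 100 * seq_along(idx) / 2000) *
      exp(-0.5 * (seq(-20, 20) / 8)^2)
  }
  s <- pcg_signal(x, 2000)
  for (env in list(hilbert_envelope(s), homomorphic_envelope(s))) {
    frame_env <- stats::approx((seq_along(env) - 0.5) / 2000, env,
                               xout = (seq_len(250) - 0.5) / 50, rule = 2)$y
    for (tc in clicks_at) {
      frame_true <- floor(tc * 50) + 1
      window <- frame_env[(frame_true - 3):(frame_true + 3)]
      expect_equal(which.max(window), 4, tolerance = 1)
    }
  }
})
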