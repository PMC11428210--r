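# build a 3-cycle label sequence at 50 frames/s, optionally shifting the
# S1/S2 intervals of the prediction by a given number of milliseconds
three_cycle_labels <- function(shift_ms = 0, frame_rate = 50) {
  shift <- round(shift_ms / 1000 * frame_rate)
  cyc <- function(off) {
    s1 <- (off + 1):(off + 5)
    s2 <- (off + 21):(off + 24)
    list(s1 = s1 + shift, sys = (off + 6):(off + 20), s2 = s2 + shift,
         dia = (off + 25):(off + 40))
  }
  lab <- rep(3L, 130)
  for (off in c(0, 40, 80)) {
    c1 <- cyc(off)
    lab[c1$sys] <- 1L
    lab[c1$dia] <- 3L
    lab[c1$s1[c1$s1 >= 1 & c1$s1 <= 130]] <- 0L
    lab[c1$s2[c1$s2 >= 1 & c1$s2 <= 130]] <- 2L
  }
  state_sequence(lab, frame_rate)
}

test_that("identical sequences give zero FP/FN everywhere", {
  truth <- three_cycle_labels()
  counts <- tolerance_match(truth, truth)
  expect_true(all(counts$fp == 0))
  expect_true(all(counts$fn == 0))
  m <- compute_metrics(counts)
  expect_equal(unname(m$macro), rep(1, 4))
})

test_that("shifts inside the tolerance window are credited, outside are not", {
  truth <- three_cycle_labels()
  # 60 ms shift: within the 100 ms (S1) and 80 ms (S2) windows
  near <- three_cycle_labels(shift_ms = 60)
  counts <- tolerance_match(near, truth)
  expect_equal(unname(counts$fn["S1"]), 0)
  expect_equal(unname(counts$fp["S1"]), 0)
  expect_equal(unname(counts$fn["S2"]), 0)

  # 150 ms (S1) / 120 ms (S2) shift: outside both windows -> FN and FP
  far <- three_cycle_labels(shift_ms = 150)
  counts_far <- tolerance_match(far, truth)
  expect_gt(unname(counts_far$fn["S1"]), 0)
  expect_gt(unname(counts_far$fp["S1"]), 0)
  expect_gt(unname(counts_far$fn["S2"]), 0)
  expect_gt(unname(counts_far$fp["S2"]), 0)
})

test_that("interval-onset example: 50 ms S1 shift scores TP without FN", {
  truth <- seq_of_runs(list(3L, 50), list(0L, 5), list(1L, 15), list(2L, 4),
                       list(3L, 26))
  # prediction: S1 shifted 40 ms later (2 frames at 50 frames/s)
  pred <- seq_of_runs(list(3L, 52), list(0L, 5), list(1L, 13), list(2L, 4),
                      list(3L, 26))
  counts <- tolerance_match(pred, truth)
  expect_equal(unname(counts$fn["S1"]), 0)
  expect_equal(unname(counts$fp["S1"]), 0)
  expect_gte(unname(counts$tp["S1"]), 5)
})

test_that("metric formulas match hand arithmetic in both precision modes", {
  counts <- structure(list(
    tp = c(S1 = 90, systole = 90, S2 = 90, diastole = 90),
    fp = c(S1 = 10, systole = 10, S2 = 10, diastole = 10),
    tn = c(S1 = 880, systole = 880, S2 = 880, diastole = 880),
    fn = c(S1 = 20, systole = 20, S2 = 20, diastole = 20),
    confusion = matrix(0, 4, 4), n_frames = 1000),
    class = "confusion_counts")
  m <- compute_metrics(counts, "conventional")
  expect_equal(unname(m$macro["Se"]), 0.8182, tolerance = 1e-4)
  expect_equal(unname(m$macro["P"]), 0.9000, tolerance = 1e-4)
  expect_equal(unname(m$macro["F1"]), 0.8571, tolerance = 1e-4)
  expect_equal(unname(m$macro["Acc"]), 0.97, tolerance = 1e-4)

  mp <- compute_metrics(counts, "printed")
  expect_equal(unname(mp$macro["P"]), 880 / 890, tolerance = 1e-6)
  expect_false(isTRUE(all.equal(m$macro["P"], mp$macro["P"])))

  # against the literal oracle for random counts
  set.seed(13)
  for (rep in 1:100) {
    v <- sample(0:500, 4, replace = TRUE)
    counts$tp[] <- v[1]; counts$fp[] <- v[2]
    counts$tn[] <- v[3]; counts$fn[] <- v[4]
    for (mode in c("conventional", "printed")) {
      got <- suppressWarnings(compute_metrics(counts, mode))
      ref <- oracle_metrics(v[1], v[2], v[3], v[4], printed = mode == "printed")
      expect_equal(unname(got$macro), unname(ref), tolerance = 1e-6)
    }
  }
})

test_that("confusion matrix rows are normalized and diagonal on perfect input", {
  truth <- three_cycle_labels()
  cm <- confusion_matrix4(truth, truth)
  expect_equal(cm, diag(4), ignore_attr = TRUE)

  all_dia <- state_sequence(rep(3L, length(truth)), 50)
  cm2 <- confusion_matrix4(all_dia, truth)
  expect_equal(unname(cm2[, 4]), rep(1, 4))
  expect_equal(unname(rowSums(cm2)), rep(1, 4), tolerance = 1e-9)
})

test_that("widening tolerance windows never lowers sensitivity", {
  set.seed(14)
  for (rep in 1:20) {
    truth <- three_cycle_labels()
    # jitter each predicted S1/S2 interval independently
    pred <- as.integer(three_cycle_labels(shift_ms = sample(c(-120, -60, 0,
                                                              60, 120), 1)))
    pred_seq <- state_sequence(pred, 50)
    last_se <- -Inf
    for (tol in c(0, 40, 80, 120, 200)) {
      counts <- tolerance_match(pred_seq, truth, tol_s1 = tol, tol_s2 = tol)
      se <- compute_metrics(counts)$macro["Se"]
      expect_gte(se + 1e-12, last_se)
      last_se <- se
    }
  }
})

test_that("record order does not change pooled metrics", {
  a <- tolerance_match(three_cycle_labels(60), three_cycle_labels())
  b <- tolerance_match(three_cycle_labels(-40), three_cycle_labels())
  m_ab <- compute_metrics(pool_counts(a, b))$macro
  m_ba <- compute_metrics(pool_counts(b, a))$macro
  expect_equal(m_ab, m_ba)
})
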