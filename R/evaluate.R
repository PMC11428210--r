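# Tolerance-window scoring of predicted vs. true state sequences, the
# Acc/Se/P/F1 metric suite with macro averaging, and frame confusion
# matrices.

#' Tolerance-window confusion counts
#'
#' Frame-level one-vs-rest counting per state. For S1 and S2, crediting
#' operates on intervals (runs): each true S1/S2 interval is greedily matched
#' to the nearest unmatched predicted interval of the same state whose onset
#' lies within the state's tolerance window (100 ms for S1, 80 ms for S2 by
#' default). Frames of matched interval pairs count as TP; frames of
#' unmatched predicted intervals are FP and of unmatched true intervals FN.
#' Systole and diastole are scored frame-by-frame without tolerance.
#'
#' @param pred,truth [state_sequence] objects at the same frame rate.
#' @param tol_s1,tol_s2 Tolerance windows in ms.
#' @return A `confusion_counts` object: list with per-state `tp`, `fp`, `tn`,
#'   `fn` (named vectors over the four states) and the plain 4x4 frame
#'   `confusion` matrix (rows = truth).
#' @export
tolerance_match <- function(pred, truth, tol_s1 = 100, tol_s2 = 80) {
  fr_p <- attr(pred, "frame_rate"); fr_t <- attr(truth, "frame_rate")
  if (!isTRUE(all.equal(fr_p, fr_t))) {
    stop("frame rates differ between pred and truth", call. = FALSE)
  }
  if (length(pred) != length(truth)) {
    warning("length mismatch: truncating to the shorter sequence",
            call. = FALSE)
    n <- min(length(pred), length(truth))
    pred <- state_sequence(pred[seq_len(n)], fr_p)
    truth <- state_sequence(truth[seq_len(n)], fr_t)
  }
  fr <- fr_p
  p <- as.integer(pred); y <- as.integer(truth)
  n <- length(p)
  tol_frames <- c(tol_s1, NA, tol_s2, NA) / 1000 * fr

  states <- pcg_states()
  tp <- fp <- tn <- fn <- stats::setNames(numeric(4L), states)
  for (s in 0:3) {
    ps <- p == s; ys <- y == s
    if (s %in% c(0L, 2L) && (any(ps) || any(ys))) {
      cred <- credit_intervals(ps, ys, tol_frames[s + 1L])
      correct <- cred$correct  # frames counted as agreeing on state s
      tp[s + 1L] <- sum(correct)
      fp[s + 1L] <- sum(ps & !correct)
      fn[s + 1L] <- sum(ys & !correct)
      tn[s + 1L] <- n - tp[s + 1L] - fp[s + 1L] - fn[s + 1L]
    } else {
      tp[s + 1L] <- sum(ps & ys)
      fp[s + 1L] <- sum(ps & !ys)
      fn[s + 1L] <- sum(!ps & ys)
      tn[s + 1L] <- sum(!ps & !ys)
    }
  }
  conf <- matrix(0, 4L, 4L, dimnames = list(truth = states, pred = states))
  for (a in 0:3) for (b in 0:3) conf[a + 1L, b + 1L] <- sum(y == a & p == b)
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn, confusion = conf,
                 n_frames = n),
            class = "confusion_counts")
}

# interval-level tolerance crediting for one state: greedy one-to-one
# matching of true runs to predicted runs by onset distance <= tol (frames);
# frames belonging to a matched pair (union) are "correct".
credit_intervals <- function(ps, ys, tol) {
  runs <- function(mask) {
    r <- rle(mask)
    e <- cumsum(r$lengths)
    s <- e - r$lengths + 1L
    cbind(start = s[r$values], end = e[r$values])
  }
  pr <- runs(ps); yr <- runs(ys)
  correct <- ps & ys
  if (!nrow(pr) || !nrow(yr)) return(list(correct = correct))
  # greedy one-to-one matching in order of increasing onset distance; this
  # makes the matched set (hence Se) monotone in the tolerance width
  d <- abs(outer(yr[, "start"], pr[, "start"], `-`))
  ord <- order(d)
  used_y <- logical(nrow(yr)); used_p <- logical(nrow(pr))
  for (k in ord) {
    if (d[k] > tol + 1e-9) break
    i <- (k - 1L) %% nrow(yr) + 1L
    j <- (k - 1L) %/% nrow(yr) + 1L
    if (used_y[i] || used_p[j]) next
    used_y[i] <- TRUE; used_p[j] <- TRUE
    correct[yr[i, "start"]:yr[i, "end"]] <- TRUE
    correct[pr[j, "start"]:pr[j, "end"]] <- TRUE
  }
  list(correct = correct)
}

#' Pool confusion counts across records
#' @param ... `confusion_counts` objects (or a single list of them).
#' @return A pooled `confusion_counts`.
#' @export
pool_counts <- function(...) {
  xs <- list(...)
  if (length(xs) == 1L && !inherits(xs[[1L]], "confusion_counts")) xs <- xs[[1L]]
  out <- xs[[1L]]
  for (x in xs[-1L]) {
    out$tp <- out$tp + x$tp; out$fp <- out$fp + x$fp
    out$tn <- out$tn + x$tn; out$fn <- out$fn + x$fn
    out$confusion <- out$confusion + x$confusion
    out$n_frames <- out$n_frames + x$n_frames
  }
  out
}

#' Accuracy, sensitivity, precision and F1 from confusion counts
#'
#' Per state: `Acc = (TP + TN) / (TP + FP + TN + FN)`, `Se = TP / (TP + FN)`,
#' and `F1 = 2 Se P / (Se + P)`. `precision_mode = "conventional"` (default)
#' uses `P = TP / (TP + FP)`; `"printed"` uses `P = TN / (TN + FP)` (i.e.
#' specificity), kept for literal fidelity to that convention. Macro metrics are
#' unweighted means over the four states. Any 0/0 is defined as 0 with a
#' warning.
#'
#' @param counts A `confusion_counts`.
#' @param precision_mode `"conventional"` or `"printed"`.
#' @return A `metric_set`: list with data frame `per_state`
#'   (Acc/Se/P/F1 per state) and numeric vector `macro`.
#' @export
compute_metrics <- function(counts,
                            precision_mode = c("conventional", "printed")) {
  precision_mode <- match.arg(precision_mode)
  safe_div <- function(num, den) {
    bad <- den == 0
    if (any(bad & num != 0)) warning("zero denominator: metric set to 0",
                                     call. = FALSE)
    out <- ifelse(den == 0, 0, num / den)
    out
  }
  tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  acc <- safe_div(tp + tn, tp + fp + tn + fn)
  se <- safe_div(tp, tp + fn)
  p <- if (precision_mode == "printed") safe_div(tn, tn + fp)
       else safe_div(tp, tp + fp)
  f1 <- ifelse(se + p > 0, 2 * se * p / (se + p), 0)
  per_state <- data.frame(state = pcg_states(), Acc = acc, Se = se, P = p,
                          F1 = f1, row.names = NULL)
  macro <- c(Acc = mean(acc), Se = mean(se), P = mean(p), F1 = mean(f1))
  structure(list(per_state = per_state, macro = macro,
                 precision_mode = precision_mode),
            class = "metric_set")
}

#' @export
print.metric_set <- function(x, ...) {
  cat("<metric_set> (precision mode:", x$precision_mode, ")\n")
  print(cbind(x$per_state[1], round(x$per_state[-1], 4)))
  cat("macro:", paste(names(x$macro), round(x$macro, 4), sep = "=",
                      collapse = "  "), "\n")
  invisible(x)
}

#' Row-normalized 4x4 frame confusion matrix
#'
#' Plain frame-by-frame comparison (no tolerance windows); each row with at
#' least one true frame is normalized to sum to 1.
#'
#' @param pred,truth [state_sequence] objects of equal length.
#' @return 4x4 matrix, rows = true states, columns = predicted states.
#' @export
confusion_matrix4 <- function(pred, truth) {
  stopifnot(length(pred) == length(truth))
  p <- as.integer(pred); y <- as.integer(truth)
  conf <- matrix(0, 4L, 4L,
                 dimnames = list(truth = pcg_states(), pred = pcg_states()))
  for (a in 0:3) for (b in 0:3) conf[a + 1L, b + 1L] <- sum(y == a & p == b)
  rs <- rowSums(conf)
  conf[rs > 0, ] <- conf[rs > 0, , drop = FALSE] / rs[rs > 0]
  conf
}
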