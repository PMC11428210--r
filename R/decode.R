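# Turn frame posteriors into a clean state sequence, enumerate cardiac
# cycles (S1 onset to next S1 onset), and cut overlapping N-cycle fragments.

#' Decode frame posteriors into a state sequence
#'
#' Greedy argmax followed by removal of runs shorter than a per-state
#' minimum duration (absorbed into the longer neighbouring run, repeated to
#' a fixed point) and, optionally, projection onto the cyclic state order
#' S1 -> systole -> S2 -> diastole.
#'
#' @param posterior A `frame_posterior` (frames x 4, rows sum to 1) or plain
#'   matrix with a known `frame_rate`.
#' @param min_dur_ms Named per-state minimum run durations in ms; defaults
#'   S1 60, systole 80, S2 50, diastole 120.
#' @param frame_rate Frames per second (taken from the posterior attribute
#'   when present).
#' @param enforce_cyclic Project onto the cyclic order (default `FALSE`).
#' @return A [state_sequence].
#' @export
decode_states <- function(posterior,
                          min_dur_ms = c(S1 = 60, systole = 80, S2 = 50,
                                         diastole = 120),
                          frame_rate = attr(posterior, "frame_rate"),
                          enforce_cyclic = FALSE) {
  if (is.null(frame_rate)) stop("frame_rate required", call. = FALSE)
  labels <- max.col(posterior, ties.method = "first") - 1L
  min_frames <- pmax(1L, round(min_dur_ms[pcg_states()] * frame_rate / 1000))
  labels <- remove_short_runs(labels, min_frames)
  if (enforce_cyclic) labels <- cyclic_project(labels)
  state_sequence(labels, frame_rate)
}

# absorb runs shorter than their state's minimum into the longer neighbour,
# iterating until stable
remove_short_runs <- function(labels, min_frames) {
  repeat {
    r <- rle(labels)
    if (length(r$lengths) <= 1L) return(labels)
    short <- which(r$lengths < min_frames[r$values + 1L])
    if (!length(short)) return(labels)
    j <- short[which.min(r$lengths[short])]
    left <- if (j > 1L) r$lengths[j - 1L] else -1L
    right <- if (j < length(r$lengths)) r$lengths[j + 1L] else -1L
    r$values[j] <- if (left >= right) r$values[j - 1L] else r$values[j + 1L]
    labels <- inverse.rle(r)
  }
}

# force transitions to follow S1 -> systole -> S2 -> diastole -> S1
cyclic_project <- function(labels) {
  if (length(labels) <= 1L) return(labels)
  out <- labels
  for (t in 2L:length(out)) {
    prev <- out[t - 1L]
    if (out[t] != prev && out[t] != (prev + 1L) %% 4L) {
      out[t] <- prev
    }
  }
  out
}

#' Enumerate cardiac cycles from a state sequence
#'
#' A cycle spans one S1 onset to the next S1 onset. A leading run of S1 at
#' frame 1 is treated as partial and is not counted as an onset; the trailing
#' partial cycle (no closing S1) is dropped.
#'
#' @param states A [state_sequence].
#' @return Data frame with columns `start_s`, `end_s`, one row per complete
#'   cycle; zero rows when fewer than two S1 onsets exist.
#' @export
extract_cycles <- function(states) {
  frame_rate <- attr(states, "frame_rate")
  lab <- as.integer(states)
  if (!length(lab)) return(data.frame(start_s = numeric(0), end_s = numeric(0)))
  onset <- which(lab == 0L & c(-1L, lab[-length(lab)]) != 0L)
  # an S1 already underway at frame 1 is a partial cycle: not an onset
  onset <- onset[onset > 1L]
  if (length(onset) < 2L) {
    return(data.frame(start_s = numeric(0), end_s = numeric(0)))
  }
  data.frame(start_s = (onset[-length(onset)] - 1L) / frame_rate,
             end_s = (onset[-1L] - 1L) / frame_rate)
}

#' Cut a signal into overlapping N-cycle fragments
#'
#' Sliding window over cycle starts with stride `stride` cycles (default 1,
#' maximal overlap): fragment j spans cycles j .. j + n_cycles - 1, so
#' consecutive fragments share `n_cycles - stride` cycles.
#'
#' @param signal A [pcg_signal].
#' @param cycles Cycle table from [extract_cycles()] (columns `start_s`,
#'   `end_s`).
#' @param n_cycles Cycles per fragment (>= 1).
#' @param stride Cycle stride between fragment starts.
#' @param labels Optional [interval_labels]; each fragment then carries the
#'   events overlapping it (clipped, re-referenced to the fragment start).
#' @return List of `cycle_fragment` objects (fields `samples`, `rate`,
#'   `start_s`, `end_s`, `n_cycles`, `events`); empty (with a warning) when
#'   fewer than `n_cycles` cycles are available.
#' @export
fragment_by_cycles <- function(signal, cycles, n_cycles, stride = 1L,
                               labels = NULL) {
  stopifnot(inherits(signal, "pcg_signal"), n_cycles >= 1L, stride >= 1L)
  m <- nrow(cycles)
  if (m < n_cycles) {
    warning(sprintf("only %d cycle(s) available, need %d: no fragments",
                    m, n_cycles), call. = FALSE)
    return(list())
  }
  starts <- seq.int(1L, m - n_cycles + 1L, by = stride)
  lapply(starts, function(j) {
    t0 <- cycles$start_s[j]
    t1 <- cycles$end_s[j + n_cycles - 1L]
    i0 <- max(1L, floor(t0 * signal$rate) + 1L)
    i1 <- min(length(signal$samples), ceiling(t1 * signal$rate))
    ev <- NULL
    if (!is.null(labels)) {
      keep <- labels$end_s > t0 + 1e-9 & labels$start_s < t1 - 1e-9
      sub <- as.data.frame(labels)[keep, , drop = FALSE]
      if (nrow(sub)) {
        ev <- interval_labels(pmax(sub$start_s, t0) - t0,
                              pmin(sub$end_s, t1) - t0, sub$state)
      }
    }
    structure(list(samples = signal$samples[i0:i1], rate = signal$rate,
                   start_s = t0, end_s = t1, n_cycles = n_cycles,
                   events = ev),
              class = "cycle_fragment")
  })
}

#' @export
print.cycle_fragment <- function(x, ...) {
  cat(sprintf("<cycle_fragment> %d cycle(s), %.3f-%.3f s (%d samples)\n",
              x$n_cycles, x$start_s, x$end_s, length(x$samples)))
  invisible(x)
}

#' Fragment signal as a PCG signal slice
#' @param fragment A `cycle_fragment`.
#' @return A [pcg_signal] holding the fragment's samples.
#' @export
fragment_signal <- function(fragment) {
  pcg_signal(fragment$samples, fragment$rate,
             sprintf("fragment %.3f-%.3f s", fragment$start_s, fragment$end_s))
}
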