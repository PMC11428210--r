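# Ground-truth and decoded state annotations. The four cardiac states carry
# the fixed integer codes 0 = S1, 1 = systole, 2 = S2, 3 = diastole.

#' Cardiac state names in code order
#'
#' Code 0 is S1, 1 systole, 2 S2, 3 diastole.
#' @return Character vector of length 4.
#' @export
pcg_states <- function() c("S1", "systole", "S2", "diastole")

state_to_code <- function(state) {
  code <- match(as.character(state), pcg_states()) - 1L
  if (anyNA(code)) stop("unknown state label(s): ",
                        paste(unique(state[is.na(code)]), collapse = ", "),
                        call. = FALSE)
  code
}

code_to_state <- function(code) pcg_states()[as.integer(code) + 1L]

#' Construct interval labels
#'
#' @param start_s,end_s Numeric vectors of interval bounds in seconds.
#' @param state Character vector of states (`"S1"`, `"systole"`, `"S2"`,
#'   `"diastole"`).
#' @return A data frame of class `interval_labels` with columns
#'   `start_s`, `end_s`, `state`, sorted by `start_s`.
#' @export
interval_labels <- function(start_s, end_s, state) {
  df <- data.frame(start_s = as.numeric(start_s), end_s = as.numeric(end_s),
                   state = as.character(state), stringsAsFactors = FALSE)
  state_to_code(df$state)  # validates
  df <- df[order(df$start_s), , drop = FALSE]
  if (any(df$end_s <= df$start_s)) {
    stop("intervals must satisfy end_s > start_s", call. = FALSE)
  }
  if (nrow(df) > 1L &&
      any(df$start_s[-1L] < df$end_s[-nrow(df)] - 1e-9)) {
    stop("intervals must be non-overlapping", call. = FALSE)
  }
  rownames(df) <- NULL
  class(df) <- c("interval_labels", "data.frame")
  df
}

#' Read interval labels from CSV
#'
#' Expects a header `start_s,end_s,state`.
#' @param path CSV path.
#' @return An [interval_labels] data frame.
#' @export
read_labels <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("start_s", "end_s", "state")
  if (!all(need %in% names(df))) {
    stop("label file must have columns start_s,end_s,state", call. = FALSE)
  }
  interval_labels(df$start_s, df$end_s, df$state)
}

#' Write interval labels to CSV
#' @param labels An [interval_labels] data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_labels <- function(labels, path) {
  utils::write.csv(as.data.frame(labels)[c("start_s", "end_s", "state")],
                   path, row.names = FALSE)
  invisible(path)
}

#' Rasterize interval labels to per-frame state codes
#'
#' Each frame is labelled by the interval containing its center time
#' `(i - 0.5) / frame_rate`. Frames beyond the last interval keep the last
#' interval's state; frames before the first keep the first's.
#'
#' @param labels An [interval_labels] data frame.
#' @param n_frames Number of frames to produce.
#' @param frame_rate Frames per second.
#' @return A `state_sequence`: integer vector of codes 0..3 with attribute
#'   `frame_rate`.
#' @export
labels_to_frames <- function(labels, n_frames, frame_rate) {
  centers <- (seq_len(n_frames) - 0.5) / frame_rate
  idx <- findInterval(centers, labels$start_s)
  idx[idx < 1L] <- 1L
  idx[idx > nrow(labels)] <- nrow(labels)
  state_sequence(state_to_code(labels$state[idx]), frame_rate)
}

#' Construct a per-frame state sequence
#' @param labels Integer vector with values in 0..3.
#' @param frame_rate Frames per second.
#' @return Integer vector of class `state_sequence` with a `frame_rate`
#'   attribute.
#' @export
state_sequence <- function(labels, frame_rate) {
  labels <- as.integer(labels)
  if (length(labels) && (min(labels) < 0L || max(labels) > 3L)) {
    stop("state codes must be in 0..3", call. = FALSE)
  }
  structure(labels, frame_rate = as.numeric(frame_rate),
            class = "state_sequence")
}

#' Convert a per-frame state sequence to intervals
#'
#' Consecutive runs of the same state become one interval; bounds fall on
#' frame edges.
#'
#' @param states A [state_sequence].
#' @param frame_rate Frames per second (default: the sequence's attribute).
#' @return An [interval_labels] data frame.
#' @export
frames_to_intervals <- function(states, frame_rate = attr(states, "frame_rate")) {
  r <- rle(as.integer(states))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  interval_labels(starts / frame_rate, ends / frame_rate,
                  code_to_state(r$values))
}
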