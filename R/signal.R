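#' Construct a PCG signal
#'
#' A `pcg_signal` is the basic container of the package: a mono, real-valued
#' waveform with its sampling rate and a free-text provenance identifier.
#'
#' @param samples Numeric vector of dimensionless amplitudes; must be finite.
#' @param rate Sampling rate in samples/second; must be positive.
#' @param source_id Free-text provenance tag (file name, simulator seed, ...).
#' @return An object of class `pcg_signal` with fields `samples`, `rate`,
#'   `source_id`.
#' @export
#' @examples
#' s <- pcg_signal(sin(2 * pi * 50 * seq(0, 1, by = 1 / 2000)), 2000)
#' duration(s)
pcg_signal <- function(samples, rate, source_id = "") {
  samples <- as.numeric(samples)
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0) {
    stop("`rate` must be a single positive number", call. = FALSE)
  }
  if (length(samples) && !all(is.finite(samples))) {
    stop("`samples` must be finite", call. = FALSE)
  }
  structure(
    list(samples = samples, rate = as.numeric(rate),
         source_id = as.character(source_id)),
    class = "pcg_signal"
  )
}

#' @export
print.pcg_signal <- function(x, ...) {
  cat(sprintf("<pcg_signal> %d samples @ %g Hz (%.3f s)%s\n",
              length(x$samples), x$rate, duration(x),
              if (nzchar(x$source_id)) paste0(" [", x$source_id, "]") else ""))
  invisible(x)
}

#' @export
length.pcg_signal <- function(x) length(x$samples)

#' Duration of a signal in seconds
#' @param signal A `pcg_signal`.
#' @return Duration in seconds.
#' @export
duration <- function(signal) {
  stopifnot(inherits(signal, "pcg_signal"))
  length(signal$samples) / signal$rate
}

as_pcg_signal <- function(x, rate = NULL, source_id = "") {
  if (inherits(x, "pcg_signal")) return(x)
  if (is.null(rate)) stop("`rate` required when passing a bare vector", call. = FALSE)
  pcg_signal(x, rate, source_id)
}
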