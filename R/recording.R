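#' Construct a patch-clamp recording object
#'
#' A recording couples a current trace to the acquisition metadata needed by
#' the analysis pipeline: sampling interval, test voltage, replicate id,
#' condition label and (for hormone-treatment protocols) incubation time.
#'
#' @param current numeric vector of current samples, amperes (length >= 2,
#'   all finite).
#' @param dt sampling interval, seconds (> 0).
#' @param voltage_mV test-phase membrane potential, millivolts.
#' @param replicate replicate identifier.
#' @param condition condition label, e.g. `"control"` or `"IAA"`.
#' @param incubation_min incubation time in minutes, or `NA` if not
#'   applicable.
#' @param extra named list of additional metadata, carried through I/O
#'   untouched.
#' @return an object of class `"recording"`.
#' @export
recording <- function(current, dt, voltage_mV = NA_real_, replicate = NA,
                      condition = NA_character_, incubation_min = NA_real_,
                      extra = list()) {
  if (!is.numeric(current) || length(current) < 2L) {
    stop("`current` must be a numeric vector of length >= 2", call. = FALSE)
  }
  bad <- which(!is.finite(current))
  if (length(bad)) {
    stop("non-finite current sample at index ", bad[1L], call. = FALSE)
  }
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0) {
    stop("`dt` must be a single positive number (seconds)", call. = FALSE)
  }
  structure(
    list(current = as.numeric(current), dt = dt,
         voltage_mV = voltage_mV, replicate = replicate,
         condition = condition, incubation_min = incubation_min,
         extra = extra),
    class = "recording"
  )
}

#' @export
print.recording <- function(x, ...) {
  dur <- length(x$current) * x$dt
  cat(sprintf("Patch-clamp recording: %d samples, dt = %g s (%.4g s)\n",
              length(x$current), x$dt, dur))
  cat(sprintf("  voltage: %s mV | condition: %s | replicate: %s | incubation: %s min\n",
              format(x$voltage_mV), format(x$condition),
              format(x$replicate), format(x$incubation_min)))
  cat(sprintf("  current range: [%.3g, %.3g] A\n",
              min(x$current), max(x$current)))
  invisible(x)
}

#' @export
length.recording <- function(x) length(x$current)

#' Extract the analysis window from a recording
#'
#' Returns the samples used for fluctuation analysis, discarding the
#' voltage-step transients at the start and end of the sweep. Two conventions
#' are supported:
#'
#' * by count (the default): start at the first sample whose time
#'   `(i - 1) * dt` is at or after `t_start` and take exactly `n_samples`
#'   samples. On the default 80,000-sample, 5e-5 s protocol recording the
#'   defaults (`t_start = 0.501`, `n_samples = 59600`) yield exactly 59,600
#'   samples.
#' * by time: when `n_samples` is `NULL`, return samples with
#'   `t_start <= (i - 1) * dt < t_end` (half-open window).
#'
#' @param r a [recording()].
#' @param t_start window start time, seconds from the first sample.
#' @param n_samples exact number of samples to take, or `NULL` to use
#'   `t_end`.
#' @param t_end window end time (exclusive), seconds; defaults to the full
#'   recording duration.
#' @return numeric vector of current samples.
#' @examples
#' r <- recording(sin(seq_len(1000)), dt = 1e-3)
#' length(extract_analysis_window(r, t_start = 0.1, n_samples = 500))
#' @export
extract_analysis_window <- function(r, t_start = 0.501, n_samples = 59600L,
                                    t_end = NULL) {
  stopifnot(inherits(r, "recording"))
  n <- length(r$current)
  duration <- n * r$dt
  if (t_start < 0) stop("`t_start` must be >= 0", call. = FALSE)
  i0 <- ceiling(t_start / r$dt - 1e-9) + 1L  # first sample with (i-1)*dt >= t_start
  if (i0 > n) stop("window starts beyond the end of the recording", call. = FALSE)
  if (!is.null(n_samples)) {
    i1 <- i0 + as.integer(n_samples) - 1L
    if (i1 > n) {
      stop("window of ", n_samples, " samples from t = ", t_start,
           " s extends beyond the recording (", n, " samples)", call. = FALSE)
    }
  } else {
    if (is.null(t_end)) t_end <- duration
    if (t_start >= t_end) stop("`t_start` must be < `t_end`", call. = FALSE)
    if (t_end > duration + 1e-9) {
      stop("`t_end` exceeds the recording duration (", duration, " s)",
           call. = FALSE)
    }
    i1 <- i0 - 1L + sum((seq.int(i0, n) - 1) * r$dt < t_end - 1e-12)
    if (i1 < i0) stop("window contains no samples", call. = FALSE)
  }
  r$current[i0:i1]
}
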