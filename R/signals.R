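#' Regularly sampled waveform
#'
#' Container for a uniformly sampled physiological signal (ECG or BVP).
#' Sample `i` (1-based) occurs at `start_time_s + (i - 1) / fs` seconds.
#'
#' @param samples Numeric vector of sample values in device units.
#' @param fs Sampling rate in Hz (positive).
#' @param start_time_s Epoch (or scene-relative) start time in seconds.
#' @param channel Channel label, e.g. `"ecg"` or `"bvp"`.
#' @return An object of class `uniform_signal`.
#' @export
uniform_signal <- function(samples, fs, start_time_s = 0, channel = "signal") {
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0)
    stop("`fs` must be a single positive number", call. = FALSE)
  structure(
    list(samples = as.numeric(samples), fs = as.numeric(fs),
         start_time_s = as.numeric(start_time_s), channel = channel),
    class = "uniform_signal"
  )
}

#' @export
print.uniform_signal <- function(x, ...) {
  cat(sprintf("<uniform_signal> channel=%s fs=%g Hz n=%d dur=%.2f s start=%.3f\n",
              x$channel, x$fs, length(x$samples),
              length(x$samples) / x$fs, x$start_time_s))
  invisible(x)
}

#' @export
length.uniform_signal <- function(x) length(x$samples)

#' Sample times of a uniform signal
#'
#' @param x A `uniform_signal`.
#' @param relative If `TRUE`, times start at 0 instead of `start_time_s`.
#' @return Numeric vector of per-sample times in seconds.
#' @export
signal_times <- function(x, relative = FALSE) {
  t0 <- if (relative) 0 else x$start_time_s
  t0 + (seq_along(x$samples) - 1L) / x$fs
}

#' Signal duration in seconds
#' @param x A `uniform_signal`.
#' @return Duration `n / fs` in seconds.
#' @export
signal_duration <- function(x) length(x$samples) / x$fs

#' Ordered beat-event times
#'
#' R-peak or pulse-onset times on a recording's (scene-relative) time axis.
#'
#' @param times_s Strictly increasing numeric vector of event times (s).
#' @param kind Either `"r_peak"` or `"pulse_onset"`.
#' @param source_fs Sampling rate of the signal the beats were detected on.
#' @return An object of class `beat_series`.
#' @export
beat_series <- function(times_s, kind = c("r_peak", "pulse_onset"),
                        source_fs = NA_real_) {
  kind <- match.arg(kind)
  times_s <- as.numeric(times_s)
  if (length(times_s) > 1L && any(diff(times_s) <= 0))
    stop("beat times must be strictly increasing", call. = FALSE)
  structure(list(times_s = times_s, kind = kind, source_fs = source_fs),
            class = "beat_series")
}

#' @export
print.beat_series <- function(x, ...) {
  cat(sprintf("<beat_series> kind=%s n=%d span=[%.2f, %.2f] s\n",
              x$kind, length(x$times_s),
              if (length(x$times_s)) min(x$times_s) else NA,
              if (length(x$times_s)) max(x$times_s) else NA))
  invisible(x)
}

#' @export
length.beat_series <- function(x) length(x$times_s)

#' Heart-rate series
#'
#' Heart-rate values in bpm, either at beat times (`domain = "beat"`) or on a
#' uniform 4 Hz grid (`domain = "uniform_4hz"`, constant 0.25 s spacing).
#'
#' @param times_s Increasing numeric vector of times (s).
#' @param bpm Positive heart-rate values, same length as `times_s`.
#' @param domain `"beat"` or `"uniform_4hz"`.
#' @param device Device label, e.g. `"faros"` or `"e4"`.
#' @return An object of class `hr_series`.
#' @export
hr_series <- function(times_s, bpm, domain = c("beat", "uniform_4hz"),
                      device = NA_character_) {
  domain <- match.arg(domain)
  times_s <- as.numeric(times_s)
  bpm <- as.numeric(bpm)
  if (length(times_s) != length(bpm))
    stop("`times_s` and `bpm` must have equal length", call. = FALSE)
  if (domain == "uniform_4hz" && length(times_s) > 1L &&
      max(abs(diff(times_s) - 0.25)) > 1e-9)
    stop("uniform_4hz series must have constant 0.25 s spacing", call. = FALSE)
  structure(list(times_s = times_s, bpm = bpm, domain = domain,
                 device = device),
            class = "hr_series")
}

#' @export
print.hr_series <- function(x, ...) {
  cat(sprintf("<hr_series> domain=%s device=%s n=%d mean=%.1f bpm\n",
              x$domain, x$device, length(x$bpm),
              if (length(x$bpm)) mean(x$bpm) else NA))
  invisible(x)
}

#' @export
length.hr_series <- function(x) length(x$bpm)

# run code with a private RNG stream; global .Random.seed untouched
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}
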