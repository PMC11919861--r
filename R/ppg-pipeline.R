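#' Zero-phase Butterworth bandpass for BVP
#'
#' 4th-order Butterworth bandpass, 1-8 Hz, applied forward-backward
#' (zero-phase; the effective magnitude order doubles) with reflective
#' padding. Removes respiration-band drift (~0.2-0.33 Hz) and
#' high-frequency noise while preserving the pulse-rate band.
#'
#' @param sig A [uniform_signal()] with `fs >= 32` Hz.
#' @param low,high Passband edges in Hz.
#' @param order Butterworth order of each pass (default 4).
#' @return A filtered [uniform_signal()].
#' @export
butter_bandpass_bvp <- function(sig, low = 1, high = 8, order = 4) {
  fs <- sig$fs
  if (fs < 32) stop("`fs` must be >= 32 Hz for the BVP bandpass",
                    call. = FALSE)
  pad <- 3L * round(fs)
  if (length(sig$samples) < pad)
    stop("signal too short for the BVP bandpass", call. = FALSE)
  bf <- signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  y <- filt_zerophase(bf$b, bf$a, sig$samples, pad = pad)
  uniform_signal(y, fs, sig$start_time_s, sig$channel)
}

#' Pulse detection by Elgendi's two-moving-averages method
#'
#' The bandpassed BVP is clipped at zero and squared; a short moving average
#' (`w1_s`, systolic-peak scale) is compared against a long moving average
#' (`w2_s`, beat scale) plus an offset `beta * mean(squared signal)`.
#' Contiguous blocks where the short average exceeds the threshold and that
#' are at least `w1_s` wide each yield one beat: the systolic maximum of the
#' block, with the pulse onset taken as the preceding local minimum of the
#' filtered waveform.
#'
#' @param sig A bandpassed BVP [uniform_signal()].
#' @param w1_s,w2_s Moving-average windows in seconds (defaults 0.111 and
#'   0.667).
#' @param beta Offset coefficient (default 0.02).
#' @param return_kind `"onset"` (default) or `"peak"`: which event time the
#'   returned series carries.
#' @return A [beat_series()] of pulse onsets (or systolic peaks).
#' @export
detect_onsets_elgendi <- function(sig, w1_s = 0.111, w2_s = 0.667,
                                  beta = 0.02,
                                  return_kind = c("onset", "peak")) {
  return_kind <- match.arg(return_kind)
  fs <- sig$fs
  x <- sig$samples
  empty <- beat_series(numeric(0), "pulse_onset", fs)
  if (length(x) < round(w2_s * fs) + 2L) return(empty)
  z <- pmax(x, 0)
  y <- z^2
  if (max(y) <= 0) return(empty)
  w1 <- max(1L, round(w1_s * fs))
  w2 <- max(w1 + 1L, round(w2_s * fs))
  ma_peak <- moving_average(y, w1)
  ma_beat <- moving_average(y, w2)
  thr <- ma_beat + beta * mean(y)

  above <- ma_peak > thr
  d <- diff(c(FALSE, above, FALSE))
  starts <- which(d == 1L)
  ends <- which(d == -1L) - 1L
  wide <- (ends - starts + 1L) >= w1
  starts <- starts[wide]
  ends <- ends[wide]
  # amplitude floor: reject blocks far below the waveform's pulse scale
  # (filter edge transients, contact-loss noise floor)
  floor_amp <- 0.25 * sqrt(mean(y))
  strong <- mapply(function(s, e) max(x[s:e]) > floor_amp, starts, ends)
  starts <- starts[strong]
  ends <- ends[strong]
  if (!length(starts)) return(empty)

  peak_idx <- mapply(function(s, e) s + which.max(x[s:e]) - 1L, starts, ends)
  # onset: last local minimum of the waveform before the systolic peak
  onset_idx <- vapply(seq_along(peak_idx), function(k) {
    p <- peak_idx[k]
    lo <- max(1, p - round(0.5 * fs))
    seg <- x[lo:p]
    mins <- which(diff(sign(diff(seg))) > 0) + 1
    if (length(mins)) lo + mins[length(mins)] - 1
    else lo + which.min(seg) - 1
  }, numeric(1))

  idx <- if (return_kind == "onset") onset_idx else peak_idx
  # one beat per block, strictly increasing; drop duplicates from flat onsets
  ord <- order(idx)
  idx <- idx[ord][!duplicated(idx[ord])]
  beat_series(sig$start_time_s + (idx - 1L) / fs, "pulse_onset", fs)
}
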