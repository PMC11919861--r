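#' Convert beat times to a smoothed beat-domain heart-rate series
#'
#' `HR_i = 60 / (t_i - t_(i-1))` assigned at time `t_i`, then smoothed with a
#' boxcar moving average (default 3 samples) using reflective edge padding.
#'
#' @param beats A [beat_series()] with at least 2 beats.
#' @param smooth_window Boxcar length in samples; 1 disables smoothing.
#' @param device Device label carried by the result.
#' @return A beat-domain [hr_series()].
#' @export
beats_to_hr <- function(beats, smooth_window = 3, device = NA_character_) {
  t <- beats$times_s
  if (length(t) < 2L)
    stop("need at least 2 beats to compute heart rate", call. = FALSE)
  rr <- diff(t)
  if (any(rr <= 0)) stop("non-positive inter-beat interval", call. = FALSE)
  hr <- 60 / rr
  # artifact-driven impossible rates are winsorized to the plausible range
  hr <- pmin(pmax(hr, 20), 250)
  hr <- moving_average(hr, smooth_window)
  hr_series(t[-1], hr, domain = "beat", device = device)
}

#' Resample a beat-domain HR series onto a uniform 4 Hz grid
#'
#' Linear interpolation onto `grid_start_s + k * 0.25` s; grid points outside
#' the beat span hold the nearest beat's HR. Both devices are resampled onto
#' the identical grid so their samples pair one-to-one.
#'
#' @param hr A beat-domain [hr_series()] spanning at least 2 beats.
#' @param grid_start_s,grid_end_s Grid limits in seconds (inclusive).
#' @return A `uniform_4hz` [hr_series()].
#' @export
resample_4hz <- function(hr, grid_start_s, grid_end_s) {
  if (length(hr$bpm) < 1L) stop("empty heart-rate series", call. = FALSE)
  grid <- seq(grid_start_s, grid_end_s, by = 0.25)
  if (length(hr$bpm) == 1L) {
    vals <- rep(hr$bpm, length(grid))
  } else {
    vals <- stats::approx(hr$times_s, hr$bpm, xout = grid, rule = 2)$y
  }
  hr_series(grid, vals, domain = "uniform_4hz", device = hr$device)
}

#' Segment a uniform 4 Hz HR series into consecutive 10-s windows
#'
#' Windows are `[k * window_s, (k + 1) * window_s)` from the grid start
#' (scene start); a trailing incomplete window is discarded. `window_index`
#' is 0-based.
#'
#' @param hr A `uniform_4hz` [hr_series()].
#' @param window_s Window length in seconds (default 10).
#' @return A data frame with `window_index`, `start_s`, `end_s`, `first`,
#'   `last` (1-based sample indices) and `n_samples`.
#' @export
segment_windows <- function(hr, window_s = 10) {
  if (hr$domain != "uniform_4hz")
    stop("`segment_windows()` expects a uniform 4 Hz series", call. = FALSE)
  per_win <- as.integer(round(window_s * 4))
  n <- length(hr$bpm)
  n_win <- n %/% per_win
  if (n_win < 1L)
    stop("series shorter than one window", call. = FALSE)
  k <- seq_len(n_win) - 1L
  data.frame(window_index = k,
             start_s = hr$times_s[1] + k * window_s,
             end_s = hr$times_s[1] + (k + 1) * window_s,
             first = k * per_win + 1L,
             last = (k + 1L) * per_win,
             n_samples = per_win)
}

#' Mean heart rate of a window
#' @param values Numeric HR values (bpm), non-empty.
#' @return Arithmetic mean in bpm.
#' @export
mean_hr <- function(values) {
  if (!length(values)) stop("empty window", call. = FALSE)
  sum(values) / length(values)
}

#' RMSSD of a window of heart-rate values
#'
#' Root mean square of successive differences of the HR values within the
#' window: `sqrt(mean((x[i+1] - x[i])^2))`. Computed on adjacent heart-rate
#' samples (bpm), not on inter-beat intervals.
#'
#' @param values Numeric HR values (bpm), length >= 2.
#' @return RMSSD in bpm (>= 0).
#' @export
rmssd <- function(values) {
  if (length(values) < 2L) stop("need >= 2 values for RMSSD", call. = FALSE)
  sqrt(mean(diff(values)^2))
}

#' Per-window mean HR and RMSSD features
#'
#' @param hr A `uniform_4hz` [hr_series()].
#' @param window_s Window length in seconds (default 10).
#' @return A data frame with `window_index`, `start_s`, `end_s`,
#'   `mean_hr_bpm`, `rmssd_bpm`, `n_samples`.
#' @export
window_features <- function(hr, window_s = 10) {
  win <- segment_windows(hr, window_s)
  win$mean_hr_bpm <- vapply(seq_len(nrow(win)), function(i)
    mean_hr(hr$bpm[win$first[i]:win$last[i]]), numeric(1))
  win$rmssd_bpm <- vapply(seq_len(nrow(win)), function(i)
    rmssd(hr$bpm[win$first[i]:win$last[i]]), numeric(1))
  win[, c("window_index", "start_s", "end_s", "mean_hr_bpm", "rmssd_bpm",
          "n_samples")]
}

#' Construct a threshold pair directly
#'
#' @param hr_baseline_min_bpm Baseline minimum HR in bpm (> 0).
#' @param rmssd_baseline_median_bpm Baseline median window RMSSD in bpm
#'   (>= 0).
#' @param hr_multiplier,rmssd_multiplier Flagging multipliers (defaults 1.3
#'   and 0.5).
#' @return An object of class `threshold_pair`.
#' @export
threshold_pair <- function(hr_baseline_min_bpm, rmssd_baseline_median_bpm,
                           hr_multiplier = 1.3, rmssd_multiplier = 0.5) {
  if (hr_baseline_min_bpm <= 0)
    stop("`hr_baseline_min_bpm` must be positive", call. = FALSE)
  if (rmssd_baseline_median_bpm < 0)
    stop("`rmssd_baseline_median_bpm` must be >= 0", call. = FALSE)
  structure(
    list(hr_baseline_min_bpm = hr_baseline_min_bpm,
         rmssd_baseline_median_bpm = rmssd_baseline_median_bpm,
         hr_multiplier = hr_multiplier, rmssd_multiplier = rmssd_multiplier),
    class = "threshold_pair"
  )
}

#' Subject-specific distress thresholds from the baseline recording
#'
#' The mean-HR reference is the minimum of all baseline 4 Hz HR samples (the
#' subject's resting HR); the RMSSD reference is the median of the per-10-s
#' window RMSSD values over the entire baseline. An even count of windows
#' takes the mean of the two central RMSSD values.
#'
#' @param baseline_hr A `uniform_4hz` [hr_series()] covering at least 2
#'   complete windows.
#' @param hr_multiplier Flagging multiplier on the HR reference (default 1.3,
#'   i.e. +30 percent).
#' @param rmssd_multiplier Flagging multiplier on the RMSSD reference
#'   (default 0.5, i.e. -50 percent).
#' @param window_s Window length in seconds.
#' @return An object of class `threshold_pair`.
#' @export
compute_thresholds <- function(baseline_hr, hr_multiplier = 1.3,
                               rmssd_multiplier = 0.5, window_s = 10) {
  feats <- window_features(baseline_hr, window_s)
  if (nrow(feats) < 2L)
    stop("baseline too short: need >= 2 complete windows", call. = FALSE)
  structure(
    list(hr_baseline_min_bpm = min(baseline_hr$bpm),
         rmssd_baseline_median_bpm = stats::median(feats$rmssd_bpm),
         hr_multiplier = hr_multiplier,
         rmssd_multiplier = rmssd_multiplier),
    class = "threshold_pair"
  )
}

#' @export
print.threshold_pair <- function(x, ...) {
  cat(sprintf(
    "<threshold_pair> HR min=%.2f bpm (x%.2f), RMSSD median=%.3f bpm (x%.2f)\n",
    x$hr_baseline_min_bpm, x$hr_multiplier,
    x$rmssd_baseline_median_bpm, x$rmssd_multiplier))
  invisible(x)
}
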