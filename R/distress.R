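#' Flag 10-s windows against the subject's baseline thresholds
#'
#' A window's HR flag is 1 iff its mean HR strictly exceeds
#' `hr_multiplier * hr_baseline_min_bpm` (default +30 percent above the
#' baseline minimum); its RMSSD flag is 1 iff its RMSSD is strictly below
#' `rmssd_multiplier * rmssd_baseline_median_bpm` (default 50 percent below
#' the baseline median). Boundary values are not flagged. A degenerate RMSSD
#' reference of 0 yields all-zero RMSSD flags with a warning.
#'
#' @param features A window-feature data frame from [window_features()].
#' @param thr A [threshold_pair()].
#' @return A list with integer vectors `hr_flags` and `rmssd_flags`.
#' @export
flag_segments <- function(features, thr) {
  stopifnot(inherits(thr, "threshold_pair"))
  hr_cut <- thr$hr_multiplier * thr$hr_baseline_min_bpm
  rmssd_cut <- thr$rmssd_multiplier * thr$rmssd_baseline_median_bpm
  hr_flags <- as.integer(features$mean_hr_bpm > hr_cut)
  if (thr$rmssd_baseline_median_bpm == 0) {
    warning("degenerate RMSSD threshold (0): RMSSD flags are all 0",
            call. = FALSE)
    rmssd_flags <- integer(length(hr_flags))
  } else {
    rmssd_flags <- as.integer(features$rmssd_bpm < rmssd_cut)
  }
  list(hr_flags = hr_flags, rmssd_flags = rmssd_flags)
}

#' Combine HR and RMSSD flags into per-window distress levels
#'
#' `level = hr_flag + rmssd_flag`: 0 = low/absent distress, 1 = medium (one
#' marker), 2 = high (both markers).
#'
#' @param hr_flags,rmssd_flags Equal-length 0/1 vectors.
#' @return An object of class `distress_vector` (list with `window_index`,
#'   `hr_flags`, `rmssd_flags`, `level`).
#' @export
combine_flags <- function(hr_flags, rmssd_flags) {
  if (length(hr_flags) != length(rmssd_flags))
    stop("flag vectors must have equal length", call. = FALSE)
  hr_flags <- as.integer(hr_flags)
  rmssd_flags <- as.integer(rmssd_flags)
  if (length(hr_flags) && (any(!hr_flags %in% 0:1) ||
                           any(!rmssd_flags %in% 0:1)))
    stop("flags must be 0 or 1", call. = FALSE)
  structure(
    list(window_index = seq_along(hr_flags) - 1L,
         hr_flags = hr_flags, rmssd_flags = rmssd_flags,
         level = hr_flags + rmssd_flags),
    class = "distress_vector"
  )
}

#' @export
print.distress_vector <- function(x, ...) {
  cat(sprintf("<distress_vector> %d windows: [%s]\n", length(x$level),
              paste(x$level, collapse = " ")))
  invisible(x)
}

#' Count occurrences of each distress level
#'
#' @param dv A `distress_vector`.
#' @return Named integer vector with counts for levels `"0"`, `"1"`, `"2"`.
#' @export
count_levels <- function(dv) {
  lv <- factor(dv$level, levels = 0:2)
  counts <- table(lv)
  stats::setNames(as.integer(counts), c("0", "1", "2"))
}

#' Extract the three event-aligned segments for each event
#'
#' For an event at time `t`, the nominal segments are the windows covering
#' `[t-10, t)` (immediately before), `[t, t+10)` (at onset), and
#' `[t+10, t+20)` (following). Windows outside the recorded span are marked
#' absent (`NA` level); an event at the recording end keeps only its before
#' segment.
#'
#' @param dv A `distress_vector` covering the scene's windows.
#' @param event_times_s Event times in seconds (e.g. `c(120, 180, 240)`).
#' @param window_s Window length in seconds (default 10).
#' @return A list, one element per event: `time_s`, `windows` (0-based
#'   indices, `NA` if absent), `levels` (`NA` if absent).
#' @export
extract_event_segments <- function(dv, event_times_s, window_s = 10) {
  n_win <- length(dv$level)
  lapply(as.numeric(event_times_s), function(t) {
    w <- floor(c(t - window_s, t, t + window_s) / window_s)
    present <- w >= 0 & w < n_win
    levels <- rep(NA_integer_, 3L)
    levels[present] <- dv$level[w[present] + 1L]
    list(time_s = t,
         windows = ifelse(present, w, NA_integer_),
         levels = levels)
  })
}

#' Event-coincidence criteria and percentages
#'
#' A segment "detects distress" iff its level is >= 1 (medium or high).
#' For each event, `criterion_1_3` is true iff at least one of the three
#' nominal segments detects and `criterion_2_3` iff at least two do; absent
#' segments count as non-detecting and remain in the denominator of three.
#' The per-subject percentages are the share of events satisfying each
#' criterion.
#'
#' @param triplets Output of [extract_event_segments()]; each event must
#'   have at least one present segment.
#' @return An object of class `event_report`: per-event table plus
#'   `pct_1_3`, `pct_2_3` in \[0, 100\].
#' @export
event_coincidence <- function(triplets) {
  if (!length(triplets)) stop("zero events", call. = FALSE)
  per_event <- lapply(triplets, function(ev) {
    if (all(is.na(ev$levels)))
      stop("event at ", ev$time_s, " s has no present segment", call. = FALSE)
    detects <- !is.na(ev$levels) & ev$levels >= 1L
    list(time_s = ev$time_s, levels = ev$levels,
         n_absent = sum(is.na(ev$levels)),
         criterion_1_3 = sum(detects) >= 1L,
         criterion_2_3 = sum(detects) >= 2L)
  })
  c13 <- vapply(per_event, `[[`, logical(1), "criterion_1_3")
  c23 <- vapply(per_event, `[[`, logical(1), "criterion_2_3")
  structure(
    list(events = per_event,
         pct_1_3 = 100 * mean(c13),
         pct_2_3 = 100 * mean(c23)),
    class = "event_report"
  )
}

#' @export
print.event_report <- function(x, ...) {
  cat(sprintf("<event_report> %d events: 1/3 criterion %.1f%%, 2/3 criterion %.1f%%\n",
              length(x$events), x$pct_1_3, x$pct_2_3))
  invisible(x)
}
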