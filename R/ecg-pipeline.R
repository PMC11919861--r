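# mirror padding (edge sample not repeated), clamped for short inputs
reflect_pad_indices <- function(n, k1, k2) {
  pre <- if (k1 > 0) pmax(pmin(seq(k1 + 1, 2), n), 1) else integer(0)
  post <- if (k2 > 0) pmax(pmin(seq(n - 1, n - k2), n), 1) else integer(0)
  c(pre, seq_len(n), post)
}

# centered boxcar moving average with reflective edge padding
moving_average <- function(x, w) {
  w <- as.integer(w)
  n <- length(x)
  if (w <= 1L || n == 0L) return(x)
  k1 <- (w - 1L) %/% 2L
  k2 <- w - 1L - k1
  xp <- x[reflect_pad_indices(n, k1, k2)]
  cs <- cumsum(c(0, xp))
  (cs[(w + 1):(n + w)] - cs[1:n]) / w
}

# zero-phase filtering: reflective padding of `pad` samples, filter forward,
# reverse, filter again, reverse, strip padding
filt_zerophase <- function(b, a, x, pad) {
  n <- length(x)
  pad <- min(pad, n - 1L)
  idx <- reflect_pad_indices(n, pad, pad)
  xp <- x[idx]
  flt <- signal::Arma(b = as.numeric(b), a = as.numeric(a))
  y <- as.numeric(signal::filter(flt, xp))
  y <- rev(as.numeric(signal::filter(flt, rev(y))))
  y[(pad + 1):(pad + n)]
}

#' Zero-phase FIR bandpass for ECG
#'
#' Window-method (Hamming) FIR bandpass with passband 3-45 Hz and order
#' `round(0.3 * fs)` forced to the nearest even value so the filter has
#' exactly linear phase; applied forward-backward with reflective padding of
#' three filter lengths, so the net result is zero-phase and
#' length-preserving.
#'
#' @param sig A [uniform_signal()] with `fs >= 100` Hz.
#' @param low,high Passband edges in Hz.
#' @return A filtered [uniform_signal()].
#' @export
fir_bandpass_ecg <- function(sig, low = 3, high = 45) {
  fs <- sig$fs
  if (fs < 100) stop("`fs` must be >= 100 Hz for the ECG bandpass",
                     call. = FALSE)
  ord <- round(0.3 * fs)
  if (ord %% 2 == 1) ord <- ord + 1
  ntaps <- ord + 1
  if (length(sig$samples) < 3 * ntaps)
    stop("signal too short for the ECG bandpass (need >= 3 filter lengths)",
         call. = FALSE)
  b <- as.numeric(signal::fir1(ord, c(low, high) / (fs / 2), type = "pass"))
  # pin an exact spectral zero at DC: the windowed design alone leaves a
  # few-percent leak at 0 Hz with this order and a 3 Hz lower edge
  b <- b - mean(b)
  y <- filt_zerophase(b, 1, sig$samples, pad = 3L * ntaps)
  uniform_signal(y, fs, sig$start_time_s, sig$channel)
}

# local maxima of `x` strictly above `floor_`, keeping the larger of any two
# maxima closer than `min_dist` samples
local_maxima <- function(x, min_dist, floor_ = 0) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  idx <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n] &
                 x[2:(n - 1)] > floor_) + 1L
  if (length(idx) < 2L) return(idx)
  keep <- idx[1]
  for (i in idx[-1]) {
    last <- keep[length(keep)]
    if (i - last >= min_dist) keep <- c(keep, i)
    else if (x[i] > x[last]) keep[length(keep)] <- i
  }
  keep
}

#' QRS detection after Hamilton
#'
#' Adaptive-threshold QRS detection on a bandpassed ECG: differentiate,
#' rectify, 80-ms moving-average envelope, then classify envelope peaks
#' against a running detection threshold
#' `noise_avg + 0.3125 * (qrs_avg - noise_avg)` with a 200-ms refractory
#' period and a search-back at 1.5 times the running mean RR interval.
#' Detections are snapped to the local signal maximum within +-40 ms.
#'
#' @param sig A bandpassed ECG [uniform_signal()].
#' @return A [beat_series()] of R-peak times (empty for a flat signal).
#' @export
detect_qrs_hamilton <- function(sig) {
  fs <- sig$fs
  x <- sig$samples
  empty <- beat_series(numeric(0), "r_peak", fs)
  if (length(x) < fs) return(empty)
  env <- moving_average(abs(diff(x)), max(1L, round(0.08 * fs)))
  if (max(env) <= 0) return(empty)

  refr <- round(0.2 * fs)
  peaks <- local_maxima(env, min_dist = refr, floor_ = 1e-4 * max(env))
  if (!length(peaks)) return(empty)
  heights <- env[peaks]

  # running averages over the last 8 accepted QRS / noise peak heights
  init_span <- peaks <= 2 * fs
  qrs_h <- max(heights[init_span], heights[1])
  noise_h <- 0.1 * qrs_h
  qrs_hist <- qrs_h
  noise_hist <- noise_h
  qrs_idx <- integer(0)
  rr_hist <- numeric(0)
  rejected <- integer(0)

  accept <- function(i) {
    qrs_idx <<- c(qrs_idx, i)
    qrs_hist <<- utils::tail(c(qrs_hist, env[i]), 8)
    if (length(qrs_idx) > 1L) {
      rr <- diff(utils::tail(qrs_idx, 2))
      rr_hist <<- utils::tail(c(rr_hist, rr), 8)
    }
  }

  for (p in peaks) {
    thr <- mean(noise_hist) + 0.3125 * (mean(qrs_hist) - mean(noise_hist))
    last <- if (length(qrs_idx)) qrs_idx[length(qrs_idx)] else -Inf
    if (env[p] > thr && (p - last) > refr) {
      # search-back: a long gap suggests a missed beat among rejected peaks
      if (length(rr_hist) && is.finite(last) &&
          (p - last) > 1.5 * mean(rr_hist)) {
        cand <- rejected[rejected > last + refr & rejected < p - refr]
        cand <- cand[env[cand] > 0.5 * thr]
        if (length(cand)) accept(cand[which.max(env[cand])])
      }
      accept(p)
    } else {
      rejected <- c(rejected, p)
      noise_hist <- utils::tail(c(noise_hist, env[p]), 8)
    }
  }
  if (!length(qrs_idx)) return(empty)

  # snap each detection to the R apex: local max of the signal within +-40 ms
  snap <- round(0.04 * fs)
  r_idx <- vapply(qrs_idx, function(i) {
    lo <- max(1, i - snap)
    hi <- min(length(x), i + snap)
    lo + which.max(x[lo:hi]) - 1
  }, numeric(1))
  r_idx <- sort(unique(r_idx))
  # enforce refractory after snapping: keep the taller of close pairs
  if (length(r_idx) > 1L) {
    keep <- r_idx[1]
    for (i in r_idx[-1]) {
      last <- keep[length(keep)]
      if (i - last > refr) keep <- c(keep, i)
      else if (x[i] > x[last]) keep[length(keep)] <- i
    }
    r_idx <- keep
  }
  beat_series(sig$start_time_s + (r_idx - 1L) / fs, "r_peak", fs)
}

#' Template-matching R-peak correction
#'
#' Builds the mean beat template over a -100..+100 ms window around each
#' detected beat, then shifts each beat to the lag within +-50 ms that
#' maximizes the normalized cross-correlation with the template. Ordering
#' and the 200-ms refractory are preserved; if two corrected beats collide,
#' the one with the higher template correlation is kept.
#'
#' @param sig The bandpassed ECG the beats were detected on.
#' @param beats A [beat_series()] with at least 3 beats; fewer are returned
#'   unchanged with a warning.
#' @return A corrected [beat_series()].
#' @export
correct_rpeaks_template <- function(sig, beats) {
  fs <- sig$fs
  x <- sig$samples
  if (length(beats$times_s) < 3L) {
    warning("fewer than 3 beats: template correction skipped", call. = FALSE)
    return(beats)
  }
  half <- round(0.1 * fs)
  lag_max <- round(0.05 * fs)
  b_idx <- round((beats$times_s - sig$start_time_s) * fs) + 1L
  usable <- b_idx - half - lag_max >= 1L &
    b_idx + half + lag_max <= length(x)
  if (sum(usable) < 3L) {
    warning("fewer than 3 beats fully inside the record: correction skipped",
            call. = FALSE)
    return(beats)
  }
  seg <- function(i) x[(i - half):(i + half)]
  template <- rowMeans(vapply(b_idx[usable], seg, numeric(2 * half + 1)))

  corr_at <- function(i) {
    s <- seg(i)
    if (stats::sd(s) == 0) return(-Inf)
    stats::cor(s, template)
  }
  new_idx <- b_idx
  best_corr <- rep(-Inf, length(b_idx))
  for (j in seq_along(b_idx)) {
    if (!usable[j]) {
      best_corr[j] <- 0
      next
    }
    lags <- (-lag_max):lag_max
    cc <- vapply(lags, function(L) corr_at(b_idx[j] + L), numeric(1))
    k <- which.max(cc)
    new_idx[j] <- b_idx[j] + lags[k]
    best_corr[j] <- cc[k]
  }
  ord <- order(new_idx)
  new_idx <- new_idx[ord]
  best_corr <- best_corr[ord]
  refr <- round(0.2 * fs)
  keep_idx <- 1L
  for (j in seq_along(new_idx)[-1]) {
    last <- keep_idx[length(keep_idx)]
    if (new_idx[j] - new_idx[last] > refr) keep_idx <- c(keep_idx, j)
    else if (best_corr[j] > best_corr[last]) keep_idx[length(keep_idx)] <- j
  }
  new_idx <- unique(new_idx[keep_idx])
  beat_series(sig$start_time_s + (new_idx - 1L) / fs, "r_peak", fs)
}
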