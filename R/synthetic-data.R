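#' Subject profile for the synthetic session generator
#'
#' Describes one simulated subject: resting heart rate, short-term RR
#' variability, the fractional heart-rate rise and RMSSD suppression under
#' distress, and the wrist-device artifact burden.
#'
#' @param resting_hr_bpm Resting heart rate in bpm, in \[40, 180\].
#' @param hrv_sd_ms Short-term RR-interval variability (standard deviation of
#'   the RR process around its mean) in milliseconds.
#' @param distress_hr_gain Fractional HR rise at full arousal (e.g. 0.4 means
#'   +40\%). Must be >= 0.
#' @param distress_rmssd_drop Fractional suppression of RR jitter at full
#'   arousal, in \[0, 1).
#' @param artifact_rate_per_min Poisson rate of PPG motion spikes per minute.
#' @param contact_loss_prob Per-minute probability of a wrist contact-loss
#'   interval, in \[0, 1\].
#' @param subject_id Subject identifier string.
#' @param seed Integer seed making the subject's recordings reproducible.
#' @return An object of class `subject_profile`.
#' @export
subject_profile <- function(resting_hr_bpm = 70, hrv_sd_ms = 40,
                            distress_hr_gain = 0.4, distress_rmssd_drop = 0.7,
                            artifact_rate_per_min = 1, contact_loss_prob = 0.05,
                            subject_id = "S01", seed = 1L) {
  if (resting_hr_bpm < 40 || resting_hr_bpm > 180)
    stop("`resting_hr_bpm` must be in [40, 180]", call. = FALSE)
  if (hrv_sd_ms < 0) stop("`hrv_sd_ms` must be >= 0", call. = FALSE)
  if (distress_hr_gain < 0) stop("`distress_hr_gain` must be >= 0", call. = FALSE)
  if (distress_rmssd_drop < 0 || distress_rmssd_drop >= 1)
    stop("`distress_rmssd_drop` must be in [0, 1)", call. = FALSE)
  if (artifact_rate_per_min < 0)
    stop("`artifact_rate_per_min` must be >= 0", call. = FALSE)
  if (contact_loss_prob < 0 || contact_loss_prob > 1)
    stop("`contact_loss_prob` must be in [0, 1]", call. = FALSE)
  structure(
    list(resting_hr_bpm = resting_hr_bpm, hrv_sd_ms = hrv_sd_ms,
         distress_hr_gain = distress_hr_gain,
         distress_rmssd_drop = distress_rmssd_drop,
         artifact_rate_per_min = artifact_rate_per_min,
         contact_loss_prob = contact_loss_prob,
         subject_id = subject_id, seed = as.integer(seed)),
    class = "subject_profile"
  )
}

#' @export
print.subject_profile <- function(x, ...) {
  cat(sprintf(
    "<subject_profile> %s: rest=%g bpm, RR sd=%g ms, gain=%g, drop=%g, seed=%d\n",
    x$subject_id, x$resting_hr_bpm, x$hrv_sd_ms, x$distress_hr_gain,
    x$distress_rmssd_drop, x$seed))
  invisible(x)
}

# default event schedule of the interactive scene (box fall, box + suspense,
# monster; the monster event marks the end of the trial)
IS_EVENT_TIMES <- c(120, 180, 240)

# arousal envelope in [0, 1] at times t: pointwise max of phasic event-locked
# boxcars (linear ramps of `ramp_s`, hold of `response_s`) and, for the
# interactive scene, a tonic task-engagement ramp rising linearly to 1 at
# scene end (the scene escalates by design).
arousal_envelope <- function(t, scene, event_times, duration_s,
                             response_s = 20, ramp_s = 2) {
  a <- numeric(length(t))
  if (scene == "IS" && duration_s > 0)
    a <- pmax(a, pmin(pmax(t / duration_s, 0), 1))
  for (e in event_times) {
    up <- pmin(pmax((t - e) / ramp_s, 0), 1)
    down <- pmin(pmax((e + response_s + ramp_s - t) / ramp_s, 0), 1)
    a <- pmax(a, pmin(up, down))
  }
  a
}

#' Generate a ground-truth RR-interval process
#'
#' Simulates beat-to-beat RR intervals via a mean-reverting (AR(1)) Gaussian
#' jitter process around a scene-dependent target heart rate; the jitter
#' amplitude corresponds to an RR variability of `hrv_sd_ms` at rest.
#' In the interactive scene, arousal is the pointwise maximum of event-locked
#' phasic responses (linear 2-s ramps, 20-s hold after each event) and a tonic
#' ramp that rises over the scene; at arousal `a`, the target HR is multiplied
#' by `1 + distress_hr_gain * a` and RR jitter by `1 - distress_rmssd_drop * a`.
#'
#' @param profile A [subject_profile()].
#' @param scene One of `"baseline"`, `"NIS"`, `"IS"`.
#' @param duration_s Recording duration in seconds (default 240).
#' @param seed Integer seed; defaults to the profile's seed.
#' @param event_times_s Event times for the interactive scene (default
#'   `c(120, 180, 240)`); ignored (empty) for other scenes.
#' @param response_s Phasic response hold after each event, seconds.
#' @param ramp_s Linear ramp in/out duration, seconds.
#' @return An object of class `ground_truth` with fields `rr_intervals_s`,
#'   `beat_times_s`, `scene`, `event_times_s`, `true_hr_trace` and
#'   `duration_s`.
#' @export
generate_rr_process <- function(profile, scene = c("baseline", "NIS", "IS"),
                                duration_s = 240, seed = profile$seed,
                                event_times_s = IS_EVENT_TIMES,
                                response_s = 20, ramp_s = 2) {
  scene <- match.arg(scene)
  stopifnot(inherits(profile, "subject_profile"))
  if (duration_s <= 0) stop("`duration_s` must be positive", call. = FALSE)
  events <- if (scene == "IS") as.numeric(event_times_s) else numeric(0)

  rr_rest <- 60 / profile$resting_hr_bpm
  # RR jitter of hrv_sd_ms at rest, expressed as an HR-domain amplitude;
  # arousal suppresses the absolute jitter (vagal withdrawal), so the RMSSD
  # ratio under distress is (1 - distress_rmssd_drop) regardless of HR level
  sd_bpm <- profile$resting_hr_bpm * (profile$hrv_sd_ms / 1000) / rr_rest
  phi <- 0.6  # short-term memory of the AR(1) jitter

  with_seed(seed, {
    n_max <- ceiling(duration_s / rr_rest * 2.5) + 16L
    innov <- stats::rnorm(n_max)
    rr <- numeric(n_max)
    t_cur <- 0
    z <- 0
    n <- 0L
    for (i in seq_len(n_max)) {
      a <- arousal_envelope(t_cur, scene, events, duration_s,
                            response_s, ramp_s)
      z <- phi * z + sqrt(1 - phi^2) * innov[i]
      hr_i <- profile$resting_hr_bpm * (1 + profile$distress_hr_gain * a) +
        sd_bpm * (1 - profile$distress_rmssd_drop * a) * z
      hr_i <- max(hr_i, 25)
      rr_i <- 60 / hr_i
      if (t_cur + rr_i > duration_s) break
      n <- n + 1L
      rr[n] <- rr_i
      t_cur <- t_cur + rr_i
    }
    rr <- rr[seq_len(n)]
  })

  beat_times <- cumsum(rr)
  structure(
    list(rr_intervals_s = rr, beat_times_s = beat_times, scene = scene,
         event_times_s = events, true_hr_trace = 60 / rr,
         duration_s = duration_s),
    class = "ground_truth"
  )
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> scene=%s beats=%d dur=%g s events=[%s]\n",
              x$scene, length(x$beat_times_s), x$duration_s,
              paste(x$event_times_s, collapse = ", ")))
  invisible(x)
}

# fixed PQRST template: sum of Gaussians, amplitudes in mV-like units,
# centers in s relative to the R apex
ecg_template_waves <- data.frame(
  center = c(-0.20, -0.025, 0.0, 0.03, 0.22),
  amp    = c(0.12, -0.10, 1.00, -0.18, 0.30),
  width  = c(0.025, 0.010, 0.010, 0.010, 0.050)
)

#' Synthesize an ECG waveform from ground-truth beat times
#'
#' Places a fixed PQRST template (sum of Gaussians, R amplitude 1) at each
#' ground-truth beat time and adds configurable baseline wander (0.25 Hz),
#' powerline tone (50 Hz) and white noise. The R-wave apex lies within one
#' sample of each beat time.
#'
#' @param gt A `ground_truth` object.
#' @param fs Sampling rate in Hz (default 500).
#' @param noise List with elements `baseline`, `powerline`, `white`
#'   (amplitudes; standard deviation for `white`). Any may be 0.
#' @param seed Seed for the noise draws.
#' @return A [uniform_signal()] with channel `"ecg"`.
#' @export
synthesize_ecg <- function(gt, fs = 500,
                           noise = list(baseline = 0.05, powerline = 0.01,
                                        white = 0.02),
                           seed = 0L) {
  if (fs <= 0) stop("`fs` must be positive", call. = FALSE)
  beats <- gt$beat_times_s
  if (length(beats) && (min(beats) < 0 || max(beats) > gt$duration_s))
    stop("beat times outside [0, duration]", call. = FALSE)
  tpl_halfwidth <- 0.33
  if (length(beats) > 1L && min(diff(beats)) < tpl_halfwidth)
    stop("RR interval shorter than PQRST template width", call. = FALSE)

  n <- round(gt$duration_s * fs)
  x <- numeric(n)
  for (b in beats) {
    i0 <- max(1L, floor((b - tpl_halfwidth) * fs) + 1L)
    i1 <- min(n, ceiling((b + tpl_halfwidth) * fs) + 1L)
    if (i0 > i1) next
    tau <- ((i0:i1) - 1L) / fs - b
    w <- numeric(length(tau))
    for (k in seq_len(nrow(ecg_template_waves)))
      w <- w + ecg_template_waves$amp[k] *
        exp(-(tau - ecg_template_waves$center[k])^2 /
              (2 * ecg_template_waves$width[k]^2))
    x[i0:i1] <- x[i0:i1] + w
  }

  tt <- (seq_len(n) - 1L) / fs
  with_seed(seed, {
    if (isTRUE(noise$baseline > 0))
      x <- x + noise$baseline *
        sin(2 * pi * 0.25 * tt + stats::runif(1, 0, 2 * pi))
    if (isTRUE(noise$powerline > 0))
      x <- x + noise$powerline *
        sin(2 * pi * 50 * tt + stats::runif(1, 0, 2 * pi))
    if (isTRUE(noise$white > 0))
      x <- x + stats::rnorm(n, sd = noise$white)
  })
  uniform_signal(x, fs, start_time_s = 0, channel = "ecg")
}

# pulse template on tau in [0, 0.5] s: sharp systolic upstroke + dicrotic bump
bvp_template <- function(tau) {
  exp(-(tau - 0.12)^2 / (2 * 0.04^2)) +
    0.35 * exp(-(tau - 0.36)^2 / (2 * 0.07^2))
}

#' Synthesize a wrist BVP waveform from ground-truth beat times
#'
#' Places a pulse template at each beat time plus a pulse-transit delay,
#' then injects wrist-device artifacts: transient motion spikes (Poisson
#' rate `artifacts$spike_rate_per_min`) and contact-loss intervals during
#' which the waveform is replaced by a low-amplitude noise floor. Injected
#' artifact locations are attached as the `artifacts` attribute.
#'
#' @param gt A `ground_truth` object.
#' @param fs Sampling rate in Hz (default 64).
#' @param delay_s Pulse-transit delay in seconds (default 0.25).
#' @param noise List with element `white` (additive white-noise sd).
#' @param artifacts List with `spike_rate_per_min`, `contact_loss_prob`
#'   (per-minute probability), and optionally explicit `spike_times_s` /
#'   `loss_intervals_s` (2-column matrix of start, end) overriding the draws.
#' @param seed Seed for artifact and noise draws.
#' @return A [uniform_signal()] with channel `"bvp"` and attribute
#'   `artifacts` (list of `spike_times_s`, `loss_intervals_s`).
#' @export
synthesize_bvp <- function(gt, fs = 64, delay_s = 0.25,
                           noise = list(white = 0.03),
                           artifacts = list(spike_rate_per_min = 0,
                                            contact_loss_prob = 0),
                           seed = 0L) {
  if (fs <= 0) stop("`fs` must be positive", call. = FALSE)
  beats <- gt$beat_times_s
  if (length(beats) && (min(beats) < 0 || max(beats) > gt$duration_s))
    stop("beat times outside [0, duration]", call. = FALSE)

  n <- round(gt$duration_s * fs)
  x <- numeric(n)
  for (b in beats + delay_s) {
    i0 <- max(1L, floor(b * fs) + 1L)
    i1 <- min(n, ceiling((b + 0.5) * fs) + 1L)
    if (i0 > i1) next
    tau <- ((i0:i1) - 1L) / fs - b
    x[i0:i1] <- x[i0:i1] + bvp_template(tau)
  }

  spikes <- artifacts$spike_times_s
  losses <- artifacts$loss_intervals_s
  with_seed(seed, {
    if (is.null(spikes)) {
      rate <- artifacts$spike_rate_per_min %||% 0
      n_spk <- stats::rpois(1, rate * gt$duration_s / 60)
      spikes <- sort(stats::runif(n_spk, 0, gt$duration_s))
    }
    if (is.null(losses)) {
      p <- artifacts$contact_loss_prob %||% 0
      starts <- c()
      for (m in seq_len(floor(gt$duration_s / 60))) {
        if (stats::runif(1) < p) {
          dur <- stats::runif(1, 3, 8)
          s0 <- stats::runif(1, (m - 1) * 60, m * 60 - dur)
          starts <- rbind(starts, c(s0, s0 + dur))
        }
      }
      losses <- if (is.null(starts)) matrix(numeric(0), ncol = 2) else starts
    }
    losses <- matrix(as.numeric(losses), ncol = 2)
    # motion spikes: short high-amplitude transients
    tt <- (seq_len(n) - 1L) / fs
    for (s in spikes) {
      amp <- stats::runif(1, 2, 4) * sample(c(-1, 1), 1)
      i0 <- max(1L, floor((s - 0.2) * fs) + 1L)
      i1 <- min(n, ceiling((s + 0.2) * fs) + 1L)
      if (i0 <= i1)
        x[i0:i1] <- x[i0:i1] + amp * exp(-(tt[i0:i1] - s)^2 / (2 * 0.05^2))
    }
    # contact loss: waveform replaced by a low-amplitude noise floor
    for (k in seq_len(nrow(losses))) {
      i0 <- max(1L, floor(losses[k, 1] * fs) + 1L)
      i1 <- min(n, ceiling(losses[k, 2] * fs))
      if (i0 <= i1)
        x[i0:i1] <- stats::rnorm(i1 - i0 + 1L, sd = 0.02)
    }
    if (isTRUE(noise$white > 0))
      x <- x + stats::rnorm(n, sd = noise$white)
  })

  out <- uniform_signal(x, fs, start_time_s = 0, channel = "bvp")
  attr(out, "artifacts") <- list(spike_times_s = as.numeric(spikes),
                                 loss_intervals_s = losses)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate one paired session recording
#'
#' Draws a ground-truth RR process for the requested scene and renders it on
#' both devices: a clean high-SNR chest ECG at 500 Hz and a wrist BVP at
#' 64 Hz carrying the profile's artifact burden. The interactive scene
#' carries the event schedule `c(120, 180, 240)` seconds.
#'
#' @param profile A [subject_profile()].
#' @param scene One of `"baseline"`, `"NIS"`, `"IS"`.
#' @param seed Integer seed; defaults to the profile's seed offset by scene.
#' @param duration_s Recording duration in seconds (default 240).
#' @param clean If `TRUE`, suppress all device noise and artifacts.
#' @return An object of class `session_recording` with fields `subject_id`,
#'   `scene`, `ecg`, `bvp`, `ground_truth`, `duration_s`.
#' @export
generate_session <- function(profile, scene = c("baseline", "NIS", "IS"),
                             seed = NULL, duration_s = 240, clean = FALSE) {
  scene <- match.arg(scene)
  if (is.null(seed))
    seed <- profile$seed + match(scene, c("baseline", "NIS", "IS")) * 1000L
  gt <- generate_rr_process(profile, scene, duration_s = duration_s,
                            seed = seed)
  if (clean) {
    ecg <- synthesize_ecg(gt, noise = list(baseline = 0, powerline = 0,
                                           white = 0), seed = seed + 1L)
    bvp <- synthesize_bvp(gt, noise = list(white = 0),
                          artifacts = list(spike_rate_per_min = 0,
                                           contact_loss_prob = 0),
                          seed = seed + 2L)
  } else {
    ecg <- synthesize_ecg(gt, seed = seed + 1L)
    bvp <- synthesize_bvp(
      gt,
      artifacts = list(spike_rate_per_min = profile$artifact_rate_per_min,
                       contact_loss_prob = profile$contact_loss_prob),
      seed = seed + 2L)
  }
  structure(
    list(subject_id = profile$subject_id, scene = scene, ecg = ecg, bvp = bvp,
         ground_truth = gt, duration_s = duration_s),
    class = "session_recording"
  )
}

#' @export
print.session_recording <- function(x, ...) {
  cat(sprintf("<session_recording> %s/%s: %g s, ecg %g Hz, bvp %g Hz\n",
              x$subject_id, x$scene, x$duration_s, x$ecg$fs, x$bvp$fs))
  invisible(x)
}
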