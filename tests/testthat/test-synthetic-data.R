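test_that("zero-variability profile yields exactly constant RR intervals", {
  p <- const_profile(hr = 70)
  for (scene in c("baseline", "NIS", "IS")) {
    gt <- generate_rr_process(p, scene, duration_s = 60)
    expect_true(all(abs(gt$rr_intervals_s - 60 / 70) < 1e-12))
  }
})

test_that("RR generation is deterministic in the seed", {
  p <- subject_profile(seed = 9L)
  a <- generate_rr_process(p, "IS", seed = 9L)
  b <- generate_rr_process(p, "IS", seed = 9L)
  expect_identical(a$rr_intervals_s, b$rr_intervals_s)
  c <- generate_rr_process(p, "IS", seed = 10L)
  expect_false(isTRUE(all.equal(a$rr_intervals_s, c$rr_intervals_s)))
})

test_that("profile and duration validation", {
  expect_error(subject_profile(resting_hr_bpm = 30), "40")
  expect_error(subject_profile(distress_rmssd_drop = 1), "\\[0, 1\\)")
  expect_error(subject_profile(contact_loss_prob = 1.5), "\\[0, 1\\]")
  expect_error(generate_rr_process(subject_profile(), "IS", duration_s = 0),
               "positive")
})

test_that("ground-truth HR trace is consistent with the RR intervals", {
  gt <- generate_rr_process(subject_profile(seed = 3L), "IS")
  expect_identical(gt$true_hr_trace, 60 / gt$rr_intervals_s)
  expect_true(all(diff(gt$beat_times_s) > 0))
  expect_equal(gt$beat_times_s, cumsum(gt$rr_intervals_s))
})

test_that("interactive-scene events elevate HR above 1.3x the calm minimum", {
  p <- subject_profile(resting_hr_bpm = 70, hrv_sd_ms = 40,
                       distress_hr_gain = 0.4, seed = 21L)
  gt_is <- generate_rr_process(p, "IS", seed = 21L)
  gt_calm <- generate_rr_process(p, "baseline", seed = 22L)
  sel <- gt_is$beat_times_s >= 120 & gt_is$beat_times_s < 140
  expect_gte(mean(gt_is$true_hr_trace[sel]),
             1.3 * min(gt_calm$true_hr_trace))
})

test_that("ground-truth features in event windows cross both detector thresholds", {
  # distress gain 0.4 and RMSSD drop 0.7, asserted on ground truth only
  for (seed in c(101L, 202L, 303L)) {
    p <- subject_profile(resting_hr_bpm = 72, hrv_sd_ms = 45,
                         distress_hr_gain = 0.4, distress_rmssd_drop = 0.7,
                         seed = seed)
    base <- generate_rr_process(p, "baseline", seed = seed)
    is <- generate_rr_process(p, "IS", seed = seed + 1L)
    hr_min <- min(base$true_hr_trace)
    win_rmssd <- vapply(seq(0, 230, 10), function(s) {
      v <- base$true_hr_trace[base$beat_times_s >= s & base$beat_times_s < s + 10]
      sqrt(mean(diff(v)^2))
    }, numeric(1))
    med <- stats::median(win_rmssd)
    for (w0 in c(130, 190)) {  # hold part of the response windows
      v <- is$true_hr_trace[is$beat_times_s >= w0 & is$beat_times_s < w0 + 10]
      expect_gt(mean(v), 1.3 * hr_min)
      expect_lt(sqrt(mean(diff(v)^2)), 0.5 * med)
    }
  }
})

test_that("ECG synthesis places R apices at the beat times", {
  gt <- manual_gt(c(1, 2, 3), duration_s = 4)
  sig <- clean_ecg(gt)
  x <- sig$samples
  big <- which(x > 0.5)
  # cluster into connected runs, one per beat
  runs <- split(big, cumsum(c(1, diff(big) > 1)))
  expect_length(runs, 3L)
  apex <- vapply(runs, function(r) (r[which.max(x[r])] - 1) / sig$fs,
                 numeric(1))
  expect_true(all(abs(apex - c(1, 2, 3)) <= 0.002))
})

test_that("a 60-bpm 240-s ground truth renders 240 +/- 1 R peaks", {
  gt <- generate_rr_process(const_profile(hr = 60), "baseline",
                            duration_s = 240)
  sig <- clean_ecg(gt)
  n_peaks <- sum(diff(sign(diff(sig$samples))) < 0 &
                   sig$samples[2:(length(sig$samples) - 1)] > 0.5)
  expect_true(abs(n_peaks - 240) <= 1)
})

test_that("white noise adds what it claims and nothing else", {
  gt <- manual_gt(c(1, 2), duration_s = 3)
  s0 <- synthesize_ecg(gt, noise = list(baseline = 0, powerline = 0,
                                        white = 0), seed = 5L)
  s1 <- synthesize_ecg(gt, noise = list(baseline = 0, powerline = 0,
                                        white = 0.05), seed = 5L)
  d <- s1$samples - s0$samples
  expect_gt(stats::sd(d), 0.04)
  expect_lt(stats::sd(d), 0.06)
  expect_lt(max(abs(d)), 6 * 0.05)
})

test_that("BVP pulse onsets lag the ECG beats by the transit delay", {
  gt <- generate_rr_process(const_profile(hr = 70, seed = 8L), "baseline",
                            duration_s = 60)
  bvp <- clean_bvp(gt)
  onsets <- detect_onsets_elgendi(butter_bandpass_bvp(bvp))
  lags <- vapply(gt$beat_times_s + 0.25, function(b)
    onsets$times_s[which.min(abs(onsets$times_s - b))] - b, numeric(1))
  expect_lt(abs(stats::median(lags)), 1 / 64 + 1e-9)
})

test_that("explicit contact-loss intervals are reported verbatim in metadata", {
  gt <- generate_rr_process(const_profile(hr = 70), "baseline",
                            duration_s = 120)
  bvp <- synthesize_bvp(gt, noise = list(white = 0),
                        artifacts = list(
                          loss_intervals_s = matrix(c(100, 110), ncol = 2),
                          spike_times_s = numeric(0)))
  meta <- attr(bvp, "artifacts")
  expect_equal(meta$loss_intervals_s, matrix(c(100, 110), ncol = 2))
  expect_length(meta$spike_times_s, 0L)
  # waveform inside the interval is a low-amplitude floor
  idx <- round(102 * 64):round(108 * 64)
  expect_lt(max(abs(bvp$samples[idx])), 0.2)
})

test_that("generate_session carries the scene's event schedule and shapes", {
  p <- const_profile(hr = 65, seed = 4L)
  is <- generate_session(p, "IS")
  expect_equal(is$ground_truth$event_times_s, c(120, 180, 240))
  base <- generate_session(p, "baseline")
  expect_length(base$ground_truth$event_times_s, 0L)
  short <- generate_session(p, "NIS", duration_s = 30)
  expect_length(short$ecg$samples, 15000L)
  expect_length(short$bvp$samples, 1920L)
  expect_error(generate_session(p, "unknown"))
})

test_that("identical (profile, scene, seed) reproduce bit-identical recordings", {
  p <- subject_profile(seed = 31L)
  a <- generate_session(p, "IS", seed = 77L)
  b <- generate_session(p, "IS", seed = 77L)
  expect_identical(a$ecg$samples, b$ecg$samples)
  expect_identical(b$bvp$samples, b$bvp$samples)
  expect_identical(attr(a$bvp, "artifacts"), attr(b$bvp, "artifacts"))
})
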