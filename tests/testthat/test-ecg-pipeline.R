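sinusoid <- function(freq, fs = 500, dur = 10) {
  uniform_signal(sin(2 * pi * freq * (0:(dur * fs - 1)) / fs), fs,
                 channel = "ecg")
}

mid_amplitude <- function(sig) {
  n <- length(sig$samples)
  max(abs(sig$samples[round(n / 4):round(3 * n / 4)]))
}

test_that("ECG bandpass passes the QRS band and rejects DC and mains", {
  expect_equal(mid_amplitude(fir_bandpass_ecg(sinusoid(10))), 1,
               tolerance = 0.05)
  dc <- uniform_signal(rep(1, 5000), 500, channel = "ecg")
  expect_lt(max(abs(fir_bandpass_ecg(dc)$samples)), 0.01)
  expect_lt(mid_amplitude(fir_bandpass_ecg(sinusoid(60))), 10^(-20 / 20))
})

test_that("forward-backward filtering is zero-phase in the passband", {
  sig <- sinusoid(10)
  out <- fir_bandpass_ecg(sig)
  n <- length(sig$samples)
  core <- 1000:4000
  lags <- -3:3
  cc <- vapply(lags, function(L)
    stats::cor(sig$samples[core], out$samples[core + L]), numeric(1))
  expect_equal(lags[which.max(cc)], 0)
  expect_length(out$samples, n)
})

test_that("too-short input for the bandpass raises an informative error", {
  short <- uniform_signal(rnorm(100), 500, channel = "ecg")
  expect_error(fir_bandpass_ecg(short), "too short")
})

test_that("QRS detection recovers every beat of clean ECG across rates", {
  for (hr in c(50, 90, 130)) {
    gt <- generate_rr_process(const_profile(hr = hr, seed = hr), "baseline",
                              duration_s = 60)
    beats <- detect_qrs_hamilton(fir_bandpass_ecg(clean_ecg(gt)))
    # recall and precision 1.0 with +-25 ms matching
    d_truth <- vapply(gt$beat_times_s, function(b)
      min(abs(beats$times_s - b)), numeric(1))
    d_det <- vapply(beats$times_s, function(b)
      min(abs(gt$beat_times_s - b)), numeric(1))
    expect_true(all(d_truth <= 0.025), label = sprintf("recall at %d bpm", hr))
    expect_true(all(d_det <= 0.025),
                label = sprintf("precision at %d bpm", hr))
  }
})

test_that("clean 70-bpm ECG yields one beat per ground-truth beat, within 10 ms", {
  gt <- generate_rr_process(const_profile(hr = 70, seed = 7L), "baseline",
                            duration_s = 60)
  beats <- detect_qrs_hamilton(fir_bandpass_ecg(clean_ecg(gt)))
  expect_equal(length(beats$times_s), length(gt$beat_times_s))
  expect_lt(max(abs(beats$times_s - gt$beat_times_s)), 0.010)
})

test_that("flat signals yield an empty beat series, not an error", {
  zero <- uniform_signal(numeric(30000), 500, channel = "ecg")
  expect_length(detect_qrs_hamilton(zero)$times_s, 0L)
})

test_that("a short noise burst does not derail the adaptive threshold", {
  gt <- generate_rr_process(const_profile(hr = 70, seed = 17L), "baseline",
                            duration_s = 60)
  sig <- clean_ecg(gt)
  burst <- round(30 * 500):round(30.5 * 500)
  sig$samples[burst] <- sig$samples[burst] +
    0.8 * sin(2 * pi * 25 * seq_along(burst) / 500)
  beats <- detect_qrs_hamilton(fir_bandpass_ecg(sig))
  expect_lte(abs(length(beats$times_s) - length(gt$beat_times_s)), 1)
})

test_that("template correction recovers a displaced beat", {
  gt <- generate_rr_process(const_profile(hr = 70, seed = 5L), "baseline",
                            duration_s = 60)
  sig <- fir_bandpass_ecg(clean_ecg(gt))
  beats <- detect_qrs_hamilton(sig)
  shifted <- beats$times_s
  shifted[20] <- shifted[20] + 0.020
  corrected <- correct_rpeaks_template(sig, beat_series(shifted, "r_peak", 500))
  expect_lt(abs(corrected$times_s[20] - beats$times_s[20]), 0.004)
})

test_that("template correction is a fixed point on aligned beats and is
           invariant to a uniform shift of all beats", {
  gt <- generate_rr_process(const_profile(hr = 70, seed = 6L), "baseline",
                            duration_s = 60)
  sig <- fir_bandpass_ecg(clean_ecg(gt))
  beats <- detect_qrs_hamilton(sig)
  fixed <- correct_rpeaks_template(sig, beats)
  expect_equal(fixed$times_s, beats$times_s)
  shifted <- beat_series(beats$times_s + 0.010, "r_peak", 500)
  out <- correct_rpeaks_template(sig, shifted)
  # uniform displacement shifts the template too: relative structure intact
  expect_equal(diff(out$times_s), diff(shifted$times_s), tolerance = 1e-8)
})

test_that("fewer than 3 beats are returned unchanged with a warning", {
  gt <- generate_rr_process(const_profile(hr = 70, seed = 2L), "baseline",
                            duration_s = 60)
  sig <- fir_bandpass_ecg(clean_ecg(gt))
  two <- beat_series(c(1, 2), "r_peak", 500)
  expect_warning(out <- correct_rpeaks_template(sig, two), "3 beats")
  expect_equal(out$times_s, two$times_s)
})
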