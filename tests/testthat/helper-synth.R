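# ground truth with hand-placed beat times, for construction tests
manual_gt <- function(beat_times_s, duration_s, scene = "baseline",
                      event_times_s = numeric(0)) {
  rr <- diff(c(0, beat_times_s))
  structure(
    list(rr_intervals_s = rr, beat_times_s = beat_times_s, scene = scene,
         event_times_s = event_times_s, true_hr_trace = 60 / rr,
         duration_s = duration_s),
    class = "ground_truth"
  )
}

# constant-rate profile: deterministic RR sequence
const_profile <- function(hr = 70, seed = 1L, ...) {
  subject_profile(resting_hr_bpm = hr, hrv_sd_ms = 0, distress_hr_gain = 0,
                  seed = seed, ...)
}

clean_ecg <- function(gt, fs = 500) {
  synthesize_ecg(gt, fs = fs,
                 noise = list(baseline = 0, powerline = 0, white = 0))
}

clean_bvp <- function(gt, fs = 64) {
  synthesize_bvp(gt, fs = fs, noise = list(white = 0),
                 artifacts = list(spike_rate_per_min = 0,
                                  contact_loss_prob = 0))
}

# shared fixtures, built once per test run and cached
.fixture_env <- new.env(parent = emptyenv())

# 8 clean subjects, three scenes each, fully processed
get_clean_cohort <- function() {
  if (is.null(.fixture_env$clean)) {
    cfg <- default_run_config()
    subjects <- lapply(1:8, function(i) {
      prof <- subject_profile(resting_hr_bpm = 58 + 3.5 * i,
                              hrv_sd_ms = 28 + 3 * i,
                              subject_id = sprintf("CL%02d", i),
                              seed = 5000L + 97L * i)
      scenes <- lapply(c(baseline = "baseline", NIS = "NIS", IS = "IS"),
                       function(sc) {
        ses <- generate_session(prof, sc, clean = TRUE)
        list(session = ses,
             processed = process_scene(ses$ecg, ses$bvp, cfg))
      })
      list(profile = prof, scenes = scenes)
    })
    .fixture_env$clean <- subjects
  }
  .fixture_env$clean
}

# 16-subject cohort with default device noise/artifacts, run end to end
get_noisy_cohort <- function() {
  if (is.null(.fixture_env$noisy)) {
    dir <- file.path(tempdir(), "vrdistress-noisy-cohort")
    manifests <- simulate_cohort(16, dir, seed = 20240L)
    .fixture_env$noisy <- lapply(manifests, run_subject)
  }
  .fixture_env$noisy
}
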