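#' Default analysis configuration
#'
#' All tunables of the end-to-end pipeline with their standard settings:
#' ECG FIR bandpass 3-45 Hz of order `0.3 * fs`, BVP Butterworth 4th-order
#' 1-8 Hz, 3-sample boxcar HR smoothing, 4 Hz resampling, 10-s windows,
#' +30 percent / -50 percent threshold multipliers, interactive-scene events
#' at 120/180/240 s, 1.96 Bland-Altman limits.
#'
#' @param ... Named overrides of individual fields.
#' @return A named list of configuration values.
#' @export
default_run_config <- function(...) {
  cfg <- list(
    ecg_band = c(3, 45), ecg_order_factor = 0.3,
    bvp_band = c(1, 8), bvp_order = 4,
    smooth_window = 3, resample_hz = 4, window_s = 10,
    hr_multiplier = 1.3, rmssd_multiplier = 0.5,
    event_times_s = c(120, 180, 240),
    ba_k = 1.96, beat_anchor = "onset"
  )
  overrides <- list(...)
  cfg[names(overrides)] <- overrides
  cfg
}

#' Process one scene's raw paired streams into 4 Hz HR series
#'
#' Runs the device chains: ECG bandpass, Hamilton QRS detection and
#' template-matching correction; BVP bandpass and Elgendi onset detection;
#' beat-to-HR conversion with boxcar smoothing; resampling of both devices
#' onto the identical 4 Hz grid spanning the scene.
#'
#' @param ecg,bvp Scene-relative [uniform_signal()] objects.
#' @param config A [default_run_config()] list.
#' @return List with `hr` (list of `faros`, `e4` uniform 4 Hz series),
#'   `beats` (list of `faros`, `e4` beat series) and `features` (list of
#'   per-window feature data frames).
#' @export
process_scene <- function(ecg, bvp, config = default_run_config()) {
  ecg_f <- fir_bandpass_ecg(ecg, config$ecg_band[1], config$ecg_band[2])
  beats_f <- detect_qrs_hamilton(ecg_f)
  beats_f <- correct_rpeaks_template(ecg_f, beats_f)

  bvp_f <- butter_bandpass_bvp(bvp, config$bvp_band[1], config$bvp_band[2],
                               config$bvp_order)
  beats_e <- detect_onsets_elgendi(bvp_f, return_kind = config$beat_anchor)

  dur <- min(signal_duration(ecg), signal_duration(bvp))
  grid_end <- floor(dur / 0.25) * 0.25
  hr_f <- resample_4hz(beats_to_hr(beats_f, config$smooth_window, "faros"),
                       0, grid_end)
  hr_e <- resample_4hz(beats_to_hr(beats_e, config$smooth_window, "e4"),
                       0, grid_end)
  list(hr = list(faros = hr_f, e4 = hr_e),
       beats = list(faros = beats_f, e4 = beats_e),
       features = list(faros = window_features(hr_f, config$window_s),
                       e4 = window_features(hr_e, config$window_s)))
}

#' Run the full analysis for one subject
#'
#' Loads all scenes from the manifest, derives per-device thresholds from
#' the baseline, computes distress vectors and level counts for every scene,
#' the event-coincidence report for the interactive scene, and per-scene
#' device-agreement reports. Deterministic given the input files.
#'
#' @param manifest A manifest path or the list returned by [read_manifest()].
#' @param config A [default_run_config()] list.
#' @return A subject report bundle (list) with `subject_id`, `thresholds`,
#'   `scenes` (per scene: features, distress vectors, level counts,
#'   agreement report, event report for the interactive scene), and
#'   `skipped` (scenes dropped with their failure reason).
#' @export
run_subject <- function(manifest, config = default_run_config()) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  if (!"baseline" %in% names(manifest$scenes))
    stop("manifest has no baseline scene: cannot compute thresholds",
         call. = FALSE)

  processed <- list()
  skipped <- list()
  for (scene in names(manifest$scenes)) {
    res <- tryCatch({
      sc <- load_scene(manifest$scenes[[scene]])
      out <- process_scene(sc$ecg, sc$bvp, config)
      out$event_times_s <- sc$event_times_s
      out
    }, error = function(e) e)
    if (inherits(res, "error")) {
      if (scene == "baseline")
        stop("baseline scene failed: ", conditionMessage(res), call. = FALSE)
      skipped[[scene]] <- conditionMessage(res)
      message("scene ", scene, " skipped: ", conditionMessage(res))
    } else {
      processed[[scene]] <- res
    }
  }

  thresholds <- lapply(processed$baseline$hr, function(hr)
    compute_thresholds(hr, config$hr_multiplier, config$rmssd_multiplier,
                       config$window_s))

  scenes <- lapply(names(processed), function(scene) {
    p <- processed[[scene]]
    per_dev <- lapply(c(faros = "faros", e4 = "e4"), function(dev) {
      flags <- flag_segments(p$features[[dev]], thresholds[[dev]])
      dv <- combine_flags(flags$hr_flags, flags$rmssd_flags)
      ev <- NULL
      if (length(p$event_times_s)) {
        segs <- extract_event_segments(dv, p$event_times_s, config$window_s)
        ev <- event_coincidence(segs)
      }
      list(features = p$features[[dev]], distress = dv,
           level_counts = count_levels(dv), event_report = ev)
    })
    agreement <- agreement_report(p$hr$faros, p$hr$e4, config$ba_k)
    list(scene = scene, devices = per_dev, agreement = agreement,
         hr = p$hr)
  })
  names(scenes) <- names(processed)

  structure(
    list(subject_id = manifest$subject_id, thresholds = thresholds,
         scenes = scenes, skipped = skipped, config = config),
    class = "subject_report"
  )
}

#' @export
print.subject_report <- function(x, ...) {
  cat(sprintf("<subject_report> %s: scenes [%s]%s\n", x$subject_id,
              paste(names(x$scenes), collapse = ", "),
              if (length(x$skipped))
                paste0(", skipped [", paste(names(x$skipped), collapse = ", "),
                       "]") else ""))
  invisible(x)
}

#' Aggregate subject bundles into a cohort report
#'
#' Builds the cohort tables (mean and SD across subjects of per-scene SNR,
#' correlations, MAE/RMSE, distress-level counts, and event percentages) and
#' compares the devices' interactive-scene distress-level counts with the
#' paired Wilcoxon signed-rank test and Cliff's delta per level.
#'
#' @param bundles List of `subject_report` objects (>= 2 subjects).
#' @return An object of class `cohort_report`.
#' @export
run_cohort <- function(bundles) {
  if (length(bundles) < 2L) stop("need >= 2 subjects", call. = FALSE)

  rows <- list()
  for (b in bundles) {
    for (sc in names(b$scenes)) {
      s <- b$scenes[[sc]]
      a <- s$agreement
      for (dev in c("faros", "e4")) {
        cnt <- s$devices[[dev]]$level_counts
        ev <- s$devices[[dev]]$event_report
        rows[[length(rows) + 1L]] <- data.frame(
          subject = b$subject_id, scene = sc, device = dev,
          snr_db = unname(a$snr_db[if (dev == "faros") "ref" else "test"]),
          pearson_r = a$pearson_r, spearman_rho = a$spearman_rho,
          mae_bpm = a$mae_bpm, rmse_bpm = a$rmse_bpm,
          ba_bias_bpm = a$ba_bias_bpm,
          low = cnt[["0"]], medium = cnt[["1"]], high = cnt[["2"]],
          pct_1_3 = if (is.null(ev)) NA_real_ else ev$pct_1_3,
          pct_2_3 = if (is.null(ev)) NA_real_ else ev$pct_2_3)
      }
    }
  }
  per_subject <- do.call(rbind, rows)

  agg <- function(df, value) {
    sp <- split(df[[value]], list(df$scene, df$device), drop = TRUE)
    data.frame(group = names(sp),
               mean = vapply(sp, mean, numeric(1)),
               sd = vapply(sp, stats::sd, numeric(1)),
               row.names = NULL)
  }
  tables <- list(
    snr = agg(per_subject, "snr_db"),
    pearson = agg(per_subject, "pearson_r"),
    spearman = agg(per_subject, "spearman_rho"),
    mae = agg(per_subject, "mae_bpm"),
    rmse = agg(per_subject, "rmse_bpm"),
    levels = do.call(rbind, lapply(c("low", "medium", "high"), function(lv)
      cbind(level = lv, agg(per_subject, lv)))),
    events = {
      is_rows <- per_subject[!is.na(per_subject$pct_1_3), ]
      rbind(cbind(criterion = "1/3", agg(is_rows, "pct_1_3")),
            cbind(criterion = "2/3", agg(is_rows, "pct_2_3")))
    }
  )

  # paired device comparison of interactive-scene level counts
  is_df <- per_subject[per_subject$scene == "IS", ]
  comparisons <- lapply(c(low = "low", medium = "medium", high = "high"),
                        function(lv) {
    wide <- merge(is_df[is_df$device == "e4", c("subject", lv)],
                  is_df[is_df$device == "faros", c("subject", lv)],
                  by = "subject", suffixes = c("_e4", "_faros"))
    e4 <- wide[[paste0(lv, "_e4")]]
    fa <- wide[[paste0(lv, "_faros")]]
    wt <- tryCatch(wilcoxon_signed_rank(e4, fa), error = function(e) {
      warning("Wilcoxon degenerate for level ", lv, ": ",
              conditionMessage(e), call. = FALSE)
      list(statistic = NA_real_, p_value = NA_real_, n = 0L,
           method = "degenerate")
    })
    cd <- cliffs_delta(e4, fa)
    list(level = lv, wilcoxon = wt, cliffs_delta = cd$delta,
         magnitude = cd$magnitude)
  })

  structure(
    list(n_subjects = length(bundles), per_subject = per_subject,
         tables = tables, comparisons = comparisons),
    class = "cohort_report"
  )
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf("<cohort_report> %d subjects\n", x$n_subjects))
  for (cmp in x$comparisons)
    cat(sprintf("  %s: W=%s p=%s delta=%.3f (%s)\n", cmp$level,
                format(cmp$wilcoxon$statistic), format(cmp$wilcoxon$p_value),
                cmp$cliffs_delta, cmp$magnitude))
  invisible(x)
}

#' Write cohort report tables to CSV
#'
#' @param report A `cohort_report`.
#' @param dir Output directory (created if missing).
#' @return Character vector of written paths, invisibly.
#' @export
write_cohort_tables <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c()
  for (nm in names(report$tables)) {
    p <- file.path(dir, paste0("cohort_", nm, ".csv"))
    utils::write.csv(report$tables[[nm]], p, row.names = FALSE)
    paths <- c(paths, p)
  }
  p <- file.path(dir, "per_subject.csv")
  utils::write.csv(report$per_subject, p, row.names = FALSE)
  invisible(c(paths, p))
}

#' Simulate a cohort of subjects on disk
#'
#' Draws subject profiles (resting HR uniform on 60-85 bpm, RR variability
#' uniform on 30-55 ms, fixed distress response) and writes each subject's
#' three scenes (baseline, NIS, IS) plus a JSON manifest in the device
#' export layout, so synthetic and real data are interchangeable.
#'
#' @param n_subjects Number of subjects.
#' @param dir Output directory.
#' @param seed Cohort master seed; each subject's seed is derived from it.
#' @param clean If `TRUE`, generate noise- and artifact-free recordings.
#' @param distress_hr_gain,distress_rmssd_drop Distress response shared by
#'   all subjects.
#' @param artifact_rate_per_min,contact_loss_prob Wrist artifact burden
#'   shared by all subjects (ignored when `clean = TRUE`).
#' @return Character vector of manifest paths.
#' @export
simulate_cohort <- function(n_subjects, dir, seed = 1L, clean = FALSE,
                            distress_hr_gain = 0.4, distress_rmssd_drop = 0.7,
                            artifact_rate_per_min = 1,
                            contact_loss_prob = 0.05) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  profiles <- with_seed(seed, {
    lapply(seq_len(n_subjects), function(i)
      subject_profile(
        resting_hr_bpm = stats::runif(1, 60, 85),
        hrv_sd_ms = stats::runif(1, 30, 55),
        distress_hr_gain = distress_hr_gain,
        distress_rmssd_drop = distress_rmssd_drop,
        artifact_rate_per_min = artifact_rate_per_min,
        contact_loss_prob = contact_loss_prob,
        subject_id = sprintf("S%02d", i),
        seed = (as.integer(seed) %% 20000L) * 100000L + i * 17L))
  })
  vapply(profiles, function(p) {
    entries <- lapply(c("baseline", "NIS", "IS"), function(sc)
      write_session(generate_session(p, sc, clean = clean), dir))
    write_manifest(p$subject_id, entries, dir)
  }, character(1))
}
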