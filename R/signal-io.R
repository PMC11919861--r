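#' Read an Empatica-style BVP CSV export
#'
#' The dialect is: line 1 a UNIX start timestamp, line 2 the sampling rate,
#' then one sample value per line.
#'
#' @param path Path to the CSV file.
#' @return A [uniform_signal()] with channel `"bvp"`.
#' @export
read_e4_bvp <- function(path) {
  sig <- read_two_line_csv(path, channel = "bvp")
  if (abs(sig$fs - 64) > 1e-6)
    warning(sprintf("expected 64 Hz BVP, file declares %g Hz", sig$fs),
            call. = FALSE)
  sig
}

#' Write a signal in the Empatica-style two-line-header CSV dialect
#'
#' @param sig A [uniform_signal()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_e4_csv <- function(sig, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%.6f", sig$start_time_s), con)
  writeLines(sprintf("%.6f", sig$fs), con)
  if (length(sig$samples))
    writeLines(formatC(sig$samples, format = "g", digits = 10), con)
  invisible(path)
}

read_two_line_csv <- function(path, channel) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2L)
    stop("malformed header in ", path, ": need timestamp (line 1) and ",
         "sampling rate (line 2)", call. = FALSE)
  start <- suppressWarnings(as.numeric(lines[1]))
  if (is.na(start))
    stop("malformed header in ", path, ": line 1 is not a timestamp",
         call. = FALSE)
  fs <- suppressWarnings(as.numeric(lines[2]))
  if (is.na(fs) || fs <= 0)
    stop("malformed header in ", path, ": line 2 is not a sampling rate",
         call. = FALSE)
  body <- lines[-(1:2)]
  body <- body[nzchar(trimws(body))]
  samples <- if (length(body)) suppressWarnings(as.numeric(body))
             else numeric(0)
  if (anyNA(samples))
    stop("non-numeric sample value in ", path, call. = FALSE)
  uniform_signal(samples, fs, start_time_s = start, channel = channel)
}

#' Read an ECG recording (two-line-header CSV or EDF)
#'
#' CSV files use the same dialect as [read_e4_bvp()] (timestamp line,
#' sampling-rate line, one sample per line). Files ending in `.edf` are read
#' with the built-in minimal EDF reader.
#'
#' @param path Path to a `.csv` or `.edf` file.
#' @param channel For multi-channel EDF, the label or index of the ECG
#'   channel; an ambiguity error is raised if several channels exist and no
#'   selector is given.
#' @return A [uniform_signal()] with channel `"ecg"`.
#' @export
read_ecg <- function(path, channel = NULL) {
  if (grepl("\\.edf$", path, ignore.case = TRUE)) {
    sig <- read_edf(path, channel = channel)
    sig$channel <- "ecg"
    return(sig)
  }
  read_two_line_csv(path, channel = "ecg")
}

#' Minimal EDF reader
#'
#' Reads European-Data-Format files written by [write_edf()] and other
#' single-rate EDF writers: fixed 256-byte header, one 256-byte header block
#' per signal, 16-bit little-endian samples with linear physical scaling.
#'
#' @param path Path to the EDF file.
#' @param channel Label or 1-based index of the channel to extract; required
#'   when the file holds more than one signal.
#' @return A [uniform_signal()].
#' @export
read_edf <- function(path, channel = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- rawToChar(readBin(con, "raw", 256L))
  fld <- function(s, from, len) trimws(substr(s, from, from + len - 1L))
  startdate <- fld(hdr, 169, 8)
  starttime <- fld(hdr, 177, 8)
  n_records <- as.integer(fld(hdr, 237, 8))
  record_dur <- as.numeric(fld(hdr, 245, 8))
  ns <- as.integer(fld(hdr, 253, 4))
  if (is.na(ns) || ns < 1L) stop("corrupt EDF header", call. = FALSE)

  sig_hdr <- rawToChar(readBin(con, "raw", 256L * ns))
  sub_fld <- function(width, block_offset) {
    vapply(seq_len(ns), function(i)
      trimws(substr(sig_hdr, block_offset + (i - 1L) * width + 1L,
                    block_offset + i * width)), "")
  }
  labels <- sub_fld(16L, 0L)
  phys_min <- as.numeric(sub_fld(8L, ns * (16L + 80L + 8L)))
  phys_max <- as.numeric(sub_fld(8L, ns * (16L + 80L + 8L + 8L)))
  dig_min <- as.numeric(sub_fld(8L, ns * (16L + 80L + 8L + 8L + 8L)))
  dig_max <- as.numeric(sub_fld(8L, ns * (16L + 80L + 8L + 8L + 8L + 8L)))
  n_per_rec <- as.integer(sub_fld(8L, ns * (16L + 80L + 8L * 5L + 80L)))

  idx <- if (ns == 1L) 1L else {
    if (is.null(channel))
      stop("multi-channel EDF: specify `channel` (label or index)",
           call. = FALSE)
    if (is.character(channel)) {
      m <- match(channel, labels)
      if (is.na(m)) stop("channel not found: ", channel, call. = FALSE)
      m
    } else as.integer(channel)
  }

  samples <- numeric(0)
  chunks <- vector("list", n_records)
  for (r in seq_len(n_records)) {
    rec <- lapply(seq_len(ns), function(i)
      readBin(con, "integer", n_per_rec[i], size = 2L, endian = "little",
              signed = TRUE))
    chunks[[r]] <- rec[[idx]]
  }
  dig <- unlist(chunks)
  scale <- (phys_max[idx] - phys_min[idx]) / (dig_max[idx] - dig_min[idx])
  phys <- phys_min[idx] + (dig - dig_min[idx]) * scale
  fs <- n_per_rec[idx] / record_dur
  start <- edf_start_seconds(startdate, starttime)
  uniform_signal(phys, fs, start_time_s = start, channel = labels[idx])
}

#' Minimal EDF writer (one signal, 1-s data records)
#'
#' @param sig A [uniform_signal()]; its sampling rate must be a positive
#'   integer so 1-second records are exact.
#' @param path Output path.
#' @param label Signal label stored in the header.
#' @return `path`, invisibly. Trailing samples that do not fill a whole 1-s
#'   record are zero-padded on write (standard EDF behaviour).
#' @export
write_edf <- function(sig, path, label = "ECG") {
  fs <- sig$fs
  if (abs(fs - round(fs)) > 1e-9)
    stop("EDF writer requires an integer sampling rate", call. = FALSE)
  fs <- as.integer(round(fs))
  x <- sig$samples
  n_rec <- as.integer(ceiling(length(x) / fs))
  pad <- n_rec * fs - length(x)
  x <- c(x, numeric(pad))
  # physical limits rounded outward to the header precision (3 decimals),
  # so the stored scale matches the digitization scale exactly
  pmin_ <- floor(min(x) * 1000) / 1000
  pmax_ <- ceiling(max(x) * 1000) / 1000
  if (pmax_ - pmin_ < 1e-3) pmax_ <- pmin_ + 1
  dmin <- -32768; dmax <- 32767
  dig <- as.integer(round((x - pmin_) / (pmax_ - pmin_) * (dmax - dmin) + dmin))

  pad_field <- function(s, width) {
    s <- substr(as.character(s), 1L, width)
    paste0(s, strrep(" ", width - nchar(s)))
  }
  t0 <- sig$start_time_s
  dt <- as.POSIXlt(t0, origin = "1970-01-01", tz = "UTC")
  header <- paste0(
    pad_field("0", 8L), pad_field("X", 80L), pad_field("X", 80L),
    pad_field(format(dt, "%d.%m.%y"), 8L),
    pad_field(format(dt, "%H.%M.%S"), 8L),
    pad_field(256L + 256L, 8L), pad_field("", 44L),
    pad_field(n_rec, 8L), pad_field("1", 8L), pad_field("1", 4L))
  sig_header <- paste0(
    pad_field(label, 16L), pad_field("synthetic", 80L), pad_field("mV", 8L),
    pad_field(sprintf("%.3f", pmin_), 8L), pad_field(sprintf("%.3f", pmax_), 8L),
    pad_field(dmin, 8L), pad_field(dmax, 8L), pad_field("", 80L),
    pad_field(fs, 8L), pad_field("", 32L))

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(header), con)
  writeBin(charToRaw(sig_header), con)
  writeBin(dig, con, size = 2L, endian = "little")
  invisible(path)
}

edf_start_seconds <- function(startdate, starttime) {
  dt <- try(as.POSIXct(paste(startdate, starttime),
                       format = "%d.%m.%y %H.%M.%S", tz = "UTC"),
            silent = TRUE)
  if (inherits(dt, "try-error") || is.na(dt)) 0 else as.numeric(dt)
}

#' Quantization step of an EDF round trip
#'
#' The worst-case absolute error introduced by 16-bit EDF storage of a signal
#' with the given physical range: half a digital step.
#'
#' @param phys_range Physical range (max - min) of the stored signal.
#' @return The half-step bound in physical units.
#' @export
edf_quantization_bound <- function(phys_range) phys_range / 65535 / 2

#' Align two uniformly sampled streams on their common wall-clock span
#'
#' Both signals are cropped to the intersection of their time spans; sampling
#' rates and the values of kept samples are unchanged.
#'
#' @param ecg,bvp [uniform_signal()] objects with overlapping spans.
#' @return A list `(ecg, bvp, common_span)`; `common_span` is `c(start, end)`
#'   in the signals' time base.
#' @export
align_streams <- function(ecg, bvp) {
  span <- function(s) c(s$start_time_s,
                        s$start_time_s + length(s$samples) / s$fs)
  s1 <- span(ecg); s2 <- span(bvp)
  start <- max(s1[1], s2[1])
  end <- min(s1[2], s2[2])
  if (end <= start) stop("streams do not overlap in time", call. = FALSE)
  crop <- function(s) {
    i0 <- ceiling((start - s$start_time_s) * s$fs - 1e-9)
    i1 <- floor((end - s$start_time_s) * s$fs - 1e-9)
    keep <- (i0:i1) + 1L
    keep <- keep[keep >= 1L & keep <= length(s$samples)]
    uniform_signal(s$samples[keep], s$fs,
                   start_time_s = s$start_time_s + (keep[1] - 1L) / s$fs,
                   channel = s$channel)
  }
  list(ecg = crop(ecg), bvp = crop(bvp), common_span = c(start, end))
}

#' Write a session recording to disk in device-export layout
#'
#' Writes the ECG as a two-line-header CSV, the BVP in the Empatica-style CSV
#' dialect, and records paths, scene start time, and event times in a JSON
#' manifest entry. Synthetic and real sessions share this layout.
#'
#' @param session A `session_recording`.
#' @param dir Output directory (created if missing).
#' @return A manifest entry (list), invisibly used by [write_manifest()].
#' @export
write_session <- function(session, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  stem <- sprintf("%s_%s", session$subject_id, session$scene)
  ecg_path <- file.path(dir, paste0(stem, "_ecg.csv"))
  bvp_path <- file.path(dir, paste0(stem, "_bvp.csv"))
  write_e4_csv(session$ecg, ecg_path)
  write_e4_csv(session$bvp, bvp_path)
  list(scene = session$scene,
       ecg = basename(ecg_path), bvp = basename(bvp_path),
       start_time_s = session$ecg$start_time_s,
       event_times_s = if (!is.null(session$ground_truth))
         session$ground_truth$event_times_s else numeric(0))
}

#' Write a per-subject session manifest as JSON
#'
#' @param subject_id Subject identifier.
#' @param entries List of per-scene entries as produced by [write_session()].
#' @param dir Directory the manifest (and session files) live in.
#' @return The manifest path, invisibly.
#' @export
write_manifest <- function(subject_id, entries, dir) {
  scenes <- vapply(entries, `[[`, "", "scene")
  if (anyDuplicated(scenes))
    stop("scene labels must be unique per subject", call. = FALSE)
  path <- file.path(dir, paste0(subject_id, "_manifest.json"))
  jsonlite::write_json(list(subject_id = subject_id, scenes = entries),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a per-subject session manifest
#'
#' @param path Path to a manifest JSON written by [write_manifest()].
#' @return A list with `subject_id`, `dir`, and per-scene `scenes` entries
#'   (scene, ecg/bvp paths resolved against the manifest directory,
#'   start_time_s, event_times_s).
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  dir <- dirname(path)
  scenes <- m$scenes
  if (is.data.frame(scenes)) scenes <- split(scenes, seq_len(nrow(scenes)))
  scenes <- lapply(scenes, function(e) {
    e <- as.list(e)
    e$ecg <- file.path(dir, e$ecg)
    e$bvp <- file.path(dir, e$bvp)
    e$event_times_s <- as.numeric(unlist(e$event_times_s))
    e
  })
  names(scenes) <- vapply(scenes, `[[`, "", "scene")
  list(subject_id = m$subject_id, dir = dir, scenes = scenes)
}

#' Load one scene's paired streams from a manifest entry
#'
#' Streams are aligned on their common span and converted to scene-relative
#' time (t = 0 at the common start).
#'
#' @param entry One element of `read_manifest(path)$scenes`.
#' @return List with `ecg`, `bvp` (scene-relative [uniform_signal()]s) and
#'   `event_times_s`.
#' @export
load_scene <- function(entry) {
  ecg <- read_ecg(entry$ecg)
  bvp <- read_e4_bvp(entry$bvp)
  al <- align_streams(ecg, bvp)
  rel <- function(s) {
    s$start_time_s <- s$start_time_s - al$common_span[1]
    s
  }
  list(ecg = rel(al$ecg), bvp = rel(al$bvp),
       event_times_s = entry$event_times_s)
}
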