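# Format layer: a minimal WFDB (format 16) signal codec for interchange,
# CSV writers for the tidy outputs, symptom-log CSV round-trip, ground
# truth as JSON, and the pipeline configuration with a provenance hash.
# No installed R package reads or writes WFDB, so the codec (header + 16-bit
# little-endian samples, gain units per mV) is implemented here.

normalize_lead <- function(labels) {
  up <- toupper(gsub("^LEAD\\s+", "", trimws(labels)))
  ref <- toupper(HOLTER_LEADS)
  idx <- match(up, ref)
  if (anyNA(idx))
    stop("unmapped channel label(s): ",
         paste(labels[is.na(idx)], collapse = ", "))
  HOLTER_LEADS[idx]
}

#' Write a recording as a WFDB record (format 16)
#'
#' One `.hea` header plus an interleaved 16-bit little-endian `.dat` at the
#' given gain (ADC units per mV); gap annotations go to a
#' `<record>.gaps.csv` sidecar.
#'
#' @param recording an [ecg_recording()].
#' @param record record name (file stem).
#' @param dir output directory.
#' @param gain ADC units per mV.
#' @return invisibly, the header path.
#' @export
write_wfdb <- function(recording, record, dir = ".", gain = 1000) {
  stopifnot(inherits(recording, "ecg_recording"))
  n <- nrow(recording$signal); nsig <- ncol(recording$signal)
  adc <- round(recording$signal * gain)
  adc[adc > 32767] <- 32767; adc[adc < -32768] <- -32768
  dat <- file.path(dir, paste0(record, ".dat"))
  con <- file(dat, "wb")
  writeBin(as.integer(t(adc)), con, size = 2, endian = "little")
  close(con)
  cks <- vapply(seq_len(nsig), function(j) {
    s <- sum(adc[, j]) %% 65536
    if (s > 32767) s - 65536 else s
  }, numeric(1))
  lt <- as.POSIXlt(recording$start_time, tz = "UTC")
  hdr <- c(sprintf("%s %d %g %d %s %s", record, nsig, recording$fs, n,
                   format(recording$start_time, "%H:%M:%S"),
                   format(recording$start_time, "%d/%m/%Y")),
           sprintf("%s.dat 16 %g(0)/mV 16 0 %d %d 0 %s", record, gain,
                   adc[1, ], cks, recording$leads))
  hea <- file.path(dir, paste0(record, ".hea"))
  writeLines(hdr, hea)
  if (nrow(recording$gaps))
    utils::write.csv(recording$gaps,
                     file.path(dir, paste0(record, ".gaps.csv")),
                     row.names = FALSE)
  invisible(hea)
}

#' Read a WFDB record written by [write_wfdb()]
#'
#' Channel labels are normalized to the 12 standard names; unmapped labels
#' raise an error listing them.  Gap intervals are loaded from the sidecar
#' when present.
#'
#' @param record record name (file stem).
#' @param dir directory containing the record.
#' @return an [ecg_recording()].
#' @export
read_wfdb <- function(record, dir = ".") {
  hea <- file.path(dir, paste0(record, ".hea"))
  if (!file.exists(hea)) stop("no such record: ", hea)
  lines <- readLines(hea)
  top <- strsplit(lines[1], "\\s+")[[1]]
  nsig <- as.integer(top[2]); fs <- as.numeric(top[3])
  n <- as.integer(top[4])
  start_time <- if (length(top) >= 6)
    as.POSIXct(paste(top[6], top[5]), format = "%d/%m/%Y %H:%M:%S",
               tz = "UTC")
  else as.POSIXct("2000-01-01 00:00:00", tz = "UTC")
  sig_lines <- lines[2:(1 + nsig)]
  fields <- strsplit(sig_lines, "\\s+")
  fmt <- vapply(fields, `[[`, character(1), 2)
  if (any(fmt != "16")) stop("only WFDB format 16 is supported")
  gain <- as.numeric(sub("\\(.*$", "", vapply(fields, `[[`, character(1), 3)))
  labels <- vapply(fields, function(f) f[[length(f)]], character(1))
  leads <- normalize_lead(labels)
  dat <- file.path(dir, paste0(record, ".dat"))
  con <- file(dat, "rb")
  raw <- readBin(con, "integer", n * nsig, size = 2, endian = "little",
                 signed = TRUE)
  close(con)
  if (length(raw) != n * nsig) stop("corrupt .dat: unexpected length")
  sig <- sweep(t(matrix(raw, nsig, n)), 2, gain, "/")
  gfile <- file.path(dir, paste0(record, ".gaps.csv"))
  gaps <- if (file.exists(gfile)) utils::read.csv(gfile)
  else data.frame(start = numeric(0), end = numeric(0))
  ecg_recording(sig, fs, start_time, leads = leads, gaps = gaps,
                patient_id = record)
}

#' Read a recording from disk
#' @param path record stem (WFDB) or file path.
#' @param format `"wfdb"` (native) or `"edf"`.
#' @return an [ecg_recording()].
#' @export
read_recording <- function(path, format = c("wfdb", "edf")) {
  format <- match.arg(format)
  if (format == "edf")
    stop("EDF reading is not supported; convert to WFDB")
  read_wfdb(basename(path), dirname(path))
}

#' Write / read a symptom log as CSV
#'
#' Columns: patient_id, source (diary/button), timestamp (ISO-8601 UTC),
#' type (chest_pain, dyspnea, fatigue, other), duration_min (nullable).
#'
#' @param log symptom log data.frame.
#' @param path CSV path.
#' @return invisibly `path` / the data.frame.
#' @export
write_symptom_log <- function(log, path) {
  out <- log[, c("patient_id", "source", "timestamp", "type",
                 "duration_min")]
  out$timestamp <- format(out$timestamp, "%Y-%m-%dT%H:%M:%OS3Z", tz = "UTC")
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_symptom_log
#' @export
read_symptom_log <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  d$timestamp <- as.POSIXct(d$timestamp, format = "%Y-%m-%dT%H:%M:%OS",
                            tz = "UTC")
  d$duration_min <- suppressWarnings(as.numeric(d$duration_min))
  d
}

#' Write ground truth as JSON
#' @param truth truth list from the generators.
#' @param path JSON path.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       POSIXt = "ISO8601", dataframe = "rows")
  invisible(path)
}

#' All declared pipeline constants
#'
#' The single place where every tunable the pipeline relies on is declared;
#' round-trips losslessly through JSON.
#'
#' @return list of class `"pipeline_config"`.
#' @export
pipeline_config <- function() {
  structure(list(
    seg_len_s = SEG_LEN,
    st_window_ms = ST_WIN,
    iso_window_ms = ISO_WIN,
    t_start_after_j_ms = T_START_AFTER_J,
    hr_bin_breaks = HR_BIN_BREAKS,
    baseline_min_segments = 10,
    baseline_match_bpm = 10,
    contiguous_pairs = apply(contiguous_pairs(), 1, paste, collapse = "-"),
    event_min_run = 3,
    event_rule = "pair_stable",
    cutoff_grid_mv = c(0, 0.5, 0.005),
    burden_flag_s_day = 60,
    concurrency_window_s = 1800,
    symptom_dedup_s = 600,
    acute_types = c("chest_pain", "dyspnea"),
    day_min_usable_frac = 0.5,
    resting_band_h = c(6.5, 8.5),
    resting_symptom_margin_s = 900,
    resting_target_hr = 75,
    qtc_prolonged_ms = c(F = 460, M = 450),
    shapiro_alpha = 0.05,
    alpha = 0.05,
    bootstrap_B = 1000,
    auc_score = "normalized_burden",
    min_beats_per_window = 3,
    sdnn_min_nn = 30,
    artifact_beat_limit = 0.3
  ), class = "pipeline_config")
}

#' @rdname pipeline_config
#' @param cfg a `"pipeline_config"`.
#' @param path JSON path.
#' @export
write_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(x, class = "pipeline_config")
}

#' Provenance hash of a configuration (djb2 over its JSON form)
#' @param cfg a `"pipeline_config"`.
#' @return character hash.
#' @export
config_hash <- function(cfg) {
  s <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = NA)
  bytes <- utf8ToInt(as.character(s))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", h)
}
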