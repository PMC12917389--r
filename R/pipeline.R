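# End-to-end drivers tying the modules together.  The same downstream code
# consumes either tier: `process_recording()` reduces a waveform to the
# 10-s-grid summaries, `simulate_segments()` produces them directly.

#' Process a waveform recording through the full reduction chain
#'
#' Beat detection, delineation and classification; usability; per-10-s
#' interval medians and per-5-min SDNN; per-segment median beats; the
#' heart-rate-matched baseline library; and the ST/T deviation series.
#'
#' @param recording an [ecg_recording()].
#' @param baseline_min_segments minimum segments per baseline bin.
#' @return list of class `"holter_segments"` (same shape as
#'   [simulate_segments()]) with additional elements `beats` and
#'   `baseline`.
#' @export
process_recording <- function(recording, baseline_min_segments = 10) {
  det <- detect_beats(recording)
  beats <- delineate(recording, det)
  um <- usability_mask(recording, beats)
  iv <- interval_series(beats, recording$span_s, usable = um$usable)
  sd_df <- sdnn_series(beats, recording$span_s)
  mbs <- median_beats(recording, beats, usable = um$usable)
  lib <- build_baseline_library(mbs, min_segments = baseline_min_segments)
  dev <- measure_deviations(mbs, lib, usable = um$usable,
                            start_time = recording$start_time)
  structure(list(patient_id = recording$patient_id,
                 start_time = recording$start_time,
                 span_s = recording$span_s,
                 interval_series = iv, sdnn_series = sd_df,
                 deviations = dev,
                 usable_duration = um$usable_duration_s,
                 beats = beats, baseline = lib),
            class = "holter_segments")
}

#' @export
print.holter_segments <- function(x, ...) {
  cat(sprintf("<holter_segments> %s: %.1f h, %.1f h usable\n",
              x$patient_id, x$span_s / 3600, x$usable_duration / 3600))
  invisible(x)
}

#' Per-patient burden flags for a cohort at one parameter/cutoff
#'
#' @param cohort a [generate_cohort()] result (or any list of patients with
#'   elements `data` of class `"holter_segments"` and `label`).
#' @param parameter ischemia parameter.
#' @param cutoff cutoff (mV).
#' @param rule contiguity reading.
#' @return data.frame: patient_id, label, total_s, normalized_s_day, flag.
#' @export
cohort_burden <- function(cohort, parameter = "st_depression",
                          cutoff = 0.035, rule = "pair_stable") {
  rows <- lapply(cohort$patients, function(p) {
    ev <- detect_events(p$data$deviations, parameter, cutoff, rule = rule)
    b <- burden(ev, p$data$usable_duration)
    data.frame(patient_id = p$patient_id, label = p$label,
               total_s = b$total_s, normalized_s_day = b$normalized_s_day,
               flag = b$flag_1min, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Per-patient symptom concurrency for a cohort at one parameter/cutoff
#'
#' @inheritParams cohort_burden
#' @return data.frame: patient_id, label, n_acute, n_concurrent,
#'   pct_concurrent, flag_any_concurrent.
#' @export
cohort_concurrency <- function(cohort, parameter = "st_depression",
                               cutoff = 0.035, rule = "pair_stable") {
  rows <- lapply(cohort$patients, function(p) {
    ev <- detect_events(p$data$deviations, parameter, cutoff, rule = rule)
    sym <- merge_symptoms(p$log)
    cc <- symptom_concurrency(ev, sym, p$data$start_time)
    data.frame(patient_id = p$patient_id, label = p$label,
               n_acute = cc$n_acute, n_concurrent = cc$n_concurrent,
               pct_concurrent = cc$pct_concurrent,
               flag_any_concurrent = cc$flag_any_concurrent,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' The packaged six-patient demonstration cohort
#'
#' Four CAS and two noCAS patients, two days each, at segment resolution
#' with symptom logs — small enough for deterministic end-to-end runs.
#'
#' @param seed master seed.
#' @return a `"holter_cohort"`.
#' @export
fixture_cohort <- function(seed = 20240311L) {
  generate_cohort(4, 2, seed = seed, days = 2, level = "segments")
}
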