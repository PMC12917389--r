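#' Specification of one synthetic Holter patient
#'
#' Collects every data-generating assumption for a simulated multi-day
#' 12-lead Holter recording: circadian heart-rate and conduction-interval
#' models, the transient ST/T episode model, the symptom-reporting model, and
#' the noise/gap model.  Defaults describe the two study groups via
#' [cohort_defaults()].
#'
#' @param group `"CAS"` (coronary artery spasm) or `"noCAS"`.
#' @param days recording duration in days; the wear protocol spans 2-7 days.
#' @param start_time POSIXct (UTC) start of the recording.
#' @param hr_mesor,hr_amp,hr_acrophase circadian heart-rate cosine model:
#'   `hr(t) = mesor + amp * cos(2*pi*(h(t) - acrophase)/24)` with `h(t)` the
#'   clock hour; acrophase defaults to 15:00 so the nocturnal minimum falls
#'   at 03:00.
#' @param hr_window_sd between-10-s-window heart-rate noise SD (bpm).
#' @param rr_jitter_sd beat-to-beat RR jitter SD (ms); sets SDNN scale.
#' @param beat_jitter multiplier on the per-beat PQ/QRS/QT jitter
#'   (SDs 2/1.5/3 ms at 1); 0 makes every beat's intervals exact.
#' @param pq_base,pq_noct_inc PQ interval (ms): daytime baseline plus a
#'   nocturnal increment weighted by a cosine peaking at 04:00.
#' @param qrs_ms QRS duration (ms).
#' @param qtc_base Bazett-corrected QT (ms); per-beat QT is
#'   `qtc_base * sqrt(RR_s)` so QT tracks RR through the night.
#' @param qt_noct_inc additional nocturnal QT increment (ms) beyond the
#'   Bazett relation (0 keeps QT/sqrt(RR) constant over the day).
#' @param p_burden probability that the patient carries supra-threshold
#'   ischemic episodes (the "burden-positive" state); group defaults 0.88
#'   (CAS) and 0.44 (noCAS) reproduce the observed positive proportions at
#'   the 0.035 mV ST-depression cutoff.
#' @param episode_rate episodes per day for a burden-positive patient.
#' @param episode_amp_mean,episode_amp_sd ST-offset amplitude distribution
#'   (mV, magnitude) for burden-positive patients; centred at 0.05 mV so the
#'   0.035/0.040 mV cutoffs are discriminative.
#' @param episode_amp_min magnitude floor (mV) for burden-positive episodes.
#' @param episode_sub_amp magnitude (mV) of the sub-threshold episodes given
#'   to burden-negative patients.
#' @param episode_dur_range episode duration range (s), sampled uniformly.
#' @param episode_ramp onset/offset amplitude ramp (s).
#' @param symptom_rate merged (diary or button) background symptoms per day.
#' @param p_diary,p_button marginal probabilities that a symptom appears in
#'   the event diary / as a device button press.  Defaults 1.9/2.9 and
#'   1.4/2.9 reproduce the observed per-stream daily rates.
#' @param p_both probability a symptom appears in both streams; `NULL`
#'   (default) uses the minimal overlap `max(0, p_diary + p_button - 1)`.
#' @param p_sympt_episode probability an injected episode emits an acute
#'   symptom within +/-30 min of its onset.
#' @param dev_noise_sd per-segment, per-lead ST/T deviation noise SD (mV) on
#'   episode-free segments.
#' @param dev_noise_rho AR(1) correlation of deviation noise across
#'   consecutive 10-s segments.
#' @param artifact_frac target fraction of recording time covered by
#'   high-amplitude artifact bursts (marked unusable); together with the
#'   daily gaps the default leaves roughly 80% of the recording usable.
#' @param shower_gap_min daily electrode-off gap (min), zero-filled and
#'   annotated.
#' @param ectopic_rate fraction of beats replaced by early wide-QRS
#'   (non-sinus) beats.
#' @param noise_sd waveform white-noise SD (mV) per sample (waveform tier).
#' @param wander_amp baseline-wander amplitude (mV) (waveform tier).
#' @param seed integer seed for this patient.
#'
#' @return A validated list of class `"patient_spec"`.
#' @seealso [cohort_defaults()], [simulate_segments()], [generate_recording()]
#' @export
patient_spec <- function(group = c("CAS", "noCAS"),
                         days = 3,
                         start_time = as.POSIXct("2024-03-11 10:00:00", tz = "UTC"),
                         hr_mesor = 70, hr_amp = 8, hr_acrophase = 15,
                         hr_window_sd = 4, rr_jitter_sd = 25,
                         beat_jitter = 1,
                         pq_base = 160, pq_noct_inc = 12,
                         qrs_ms = 92,
                         qtc_base = 445, qt_noct_inc = 0,
                         p_burden = 0.5,
                         episode_rate = 2,
                         episode_amp_mean = 0.05, episode_amp_sd = 0.02,
                         episode_amp_min = 0.045,
                         episode_sub_amp = 0.02,
                         episode_dur_range = c(90, 300),
                         episode_ramp = 10,
                         symptom_rate = 2.9,
                         p_diary = 1.9 / 2.9, p_button = 1.4 / 2.9,
                         p_both = NULL,
                         p_sympt_episode = 0.3,
                         dev_noise_sd = 0.010, dev_noise_rho = 0.5,
                         artifact_frac = 0.17,
                         shower_gap_min = 20,
                         ectopic_rate = 0,
                         noise_sd = 0.008, wander_amp = 0.05,
                         seed = 1L) {
  group <- match.arg(group)
  if (is.null(p_both)) p_both <- max(0, p_diary + p_button - 1)
  spec <- list(
    group = group, days = days, start_time = start_time,
    hr_mesor = hr_mesor, hr_amp = hr_amp, hr_acrophase = hr_acrophase,
    hr_window_sd = hr_window_sd, rr_jitter_sd = rr_jitter_sd,
    beat_jitter = beat_jitter,
    pq_base = pq_base, pq_noct_inc = pq_noct_inc, qrs_ms = qrs_ms,
    qtc_base = qtc_base, qt_noct_inc = qt_noct_inc,
    p_burden = p_burden, episode_rate = episode_rate,
    episode_amp_mean = episode_amp_mean, episode_amp_sd = episode_amp_sd,
    episode_amp_min = episode_amp_min, episode_sub_amp = episode_sub_amp,
    episode_dur_range = episode_dur_range, episode_ramp = episode_ramp,
    symptom_rate = symptom_rate, p_diary = p_diary, p_button = p_button,
    p_both = p_both, p_sympt_episode = p_sympt_episode,
    dev_noise_sd = dev_noise_sd, dev_noise_rho = dev_noise_rho,
    artifact_frac = artifact_frac, shower_gap_min = shower_gap_min,
    ectopic_rate = ectopic_rate,
    noise_sd = noise_sd, wander_amp = wander_amp,
    seed = as.integer(seed)
  )
  validate_patient_spec(spec)
  structure(spec, class = "patient_spec")
}

validate_patient_spec <- function(s) {
  stopifnot(
    s$days > 0,
    s$hr_mesor > 0, s$hr_amp >= 0,
    s$rr_jitter_sd >= 0, s$hr_window_sd >= 0,
    s$episode_rate >= 0, s$symptom_rate >= 0,
    s$dev_noise_sd >= 0,
    s$artifact_frac >= 0, s$artifact_frac < 1
  )
  for (p in c("p_burden", "p_diary", "p_button", "p_both",
              "p_sympt_episode")) {
    v <- s[[p]]
    if (!is.numeric(v) || v < 0 || v > 1)
      stop(sprintf("'%s' must lie in [0, 1]", p), call. = FALSE)
  }
  if (s$p_both > min(s$p_diary, s$p_button) + 1e-12)
    stop("'p_both' cannot exceed either marginal reporting probability",
         call. = FALSE)
  if (s$days < 2 || s$days > 7)
    warning("recording duration outside the 2-7 day wear protocol",
            call. = FALSE)
  invisible(s)
}

#' Default group specifications for a two-group synthetic cohort
#'
#' The CAS group gets lower nocturnal heart rate, longer PQ and QTc, and a
#' higher burden-positive probability than the noCAS group, matching the
#' group contrasts the pipeline is designed to detect.
#'
#' @param group `"CAS"` or `"noCAS"`.
#' @param ... overrides passed on to [patient_spec()].
#' @return A `"patient_spec"`.
#' @export
cohort_defaults <- function(group = c("CAS", "noCAS"), ...) {
  group <- match.arg(group)
  base <- if (group == "CAS") {
    list(group = "CAS", hr_mesor = 68, hr_amp = 8.5,
         pq_base = 165, pq_noct_inc = 15, qtc_base = 451,
         p_burden = 0.88)
  } else {
    list(group = "noCAS", hr_mesor = 72, hr_amp = 7.5,
         pq_base = 148, pq_noct_inc = 8, qtc_base = 440,
         p_burden = 0.44)
  }
  do.call(patient_spec, utils::modifyList(base, list(...)))
}

#' Circadian heart rate (bpm) at given times
#' @param spec a `"patient_spec"`
#' @param t_s seconds since recording start
#' @return numeric bpm
#' @keywords internal
circadian_hr <- function(spec, t_s) {
  h <- clock_hour(t_s, spec$start_time)
  spec$hr_mesor + spec$hr_amp * cos(2 * pi * (h - spec$hr_acrophase) / 24)
}

# Nocturnal weight in [0, 1], peaking at 04:00
nocturnal_weight <- function(spec, t_s) {
  h <- clock_hour(t_s, spec$start_time)
  (1 + cos(2 * pi * (h - 4) / 24)) / 2
}

circadian_pq <- function(spec, t_s) {
  spec$pq_base + spec$pq_noct_inc * nocturnal_weight(spec, t_s)
}

# QT from the Bazett relation plus any extra nocturnal increment
circadian_qt <- function(spec, t_s, rr_ms) {
  spec$qtc_base * sqrt(rr_ms / 1000) +
    spec$qt_noct_inc * nocturnal_weight(spec, t_s)
}
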