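# Segment-level synthetic tier: simulates the pipeline's 10-s grid summaries
# (interval medians, SDNN, usability, ST/T deviation matrices) directly from
# the same circadian/episode/noise models as the waveform tier, so that
# multi-day and cohort-scale analyses are tractable.  Ground truth records
# every injected feature.

# AR(1) noise with stationary SD `sd` and lag-1 correlation `rho`
ar1_noise <- function(n, sd, rho) {
  if (n == 0) return(numeric(0))
  if (sd == 0) return(numeric(n))
  e <- stats::rnorm(n, 0, sd * sqrt(1 - rho^2))
  as.numeric(stats::filter(e, rho, method = "recursive"))
}

# Sample a contiguous lead set: a random adjacent pair, extended to a chain
# of three with probability p3
sample_contiguous_leads <- function(p3 = 0.5) {
  pairs <- contiguous_pairs()
  p <- pairs[sample.int(nrow(pairs), 1L), ]
  leads <- p
  if (stats::runif(1) < p3) {
    adj <- pairs[pairs[, 1] %in% leads | pairs[, 2] %in% leads, , drop = FALSE]
    ext <- setdiff(unique(as.vector(adj)), leads)
    if (length(ext)) leads <- c(leads, sample(ext, 1L))
  }
  leads
}

# Daily electrode-off and battery-change gap schedule (s since start)
gap_schedule <- function(spec, span_s) {
  gaps <- NULL
  if (spec$shower_gap_min > 0) {
    # one gap per day at 07:45 local clock
    lt <- as.POSIXlt(spec$start_time, tz = "UTC")
    h0 <- lt$hour + lt$min / 60 + lt$sec / 3600
    first <- ((7.75 - h0) %% 24) * 3600
    starts <- seq(first, span_s, by = 86400)
    starts <- starts[starts < span_s]
    if (length(starts))
      gaps <- data.frame(start = starts,
                         end = pmin(starts + spec$shower_gap_min * 60, span_s))
  }
  bat <- if (span_s > 48 * 3600)
    seq(48 * 3600, span_s - 1, by = 48 * 3600) else numeric(0)
  if (length(bat))
    gaps <- rbind(gaps, data.frame(start = bat, end = pmin(bat + 240, span_s)))
  if (is.null(gaps)) gaps <- data.frame(start = numeric(0), end = numeric(0))
  gaps[order(gaps$start), , drop = FALSE]
}

# Poisson artifact-burst schedule targeting a time fraction
artifact_schedule <- function(spec, span_s, mean_dur = 60) {
  n <- stats::rpois(1, spec$artifact_frac * span_s / mean_dur)
  if (n == 0) return(data.frame(start = numeric(0), end = numeric(0)))
  start <- sort(stats::runif(n, 0, span_s))
  dur <- stats::rexp(n, 1 / mean_dur)
  data.frame(start = start, end = pmin(start + dur, span_s))
}

# TRUE for grid segments overlapping any interval in `iv`
segments_overlapping <- function(seg_start, seg_len, iv) {
  hit <- logical(length(seg_start))
  if (nrow(iv) == 0) return(hit)
  for (k in seq_len(nrow(iv)))
    hit <- hit | (seg_start < iv$end[k] & seg_start + seg_len > iv$start[k])
  hit
}

# Episode amplitude profile averaged over each overlapped segment: trapezoid
# with linear onset/offset ramps of `ramp` seconds
episode_segment_weights <- function(seg_start, seg_len, ep_start, ep_end, ramp) {
  w <- numeric(length(seg_start))
  idx <- which(seg_start < ep_end & seg_start + seg_len > ep_start)
  if (!length(idx)) return(w)
  prof <- function(t) {
    f <- pmin(1, pmax(0, (t - ep_start) / max(ramp, 1e-9)))
    g <- pmin(1, pmax(0, (ep_end - t) / max(ramp, 1e-9)))
    pmin(f, g) * (t >= ep_start & t <= ep_end)
  }
  for (i in idx) {
    tt <- seq(seg_start[i], seg_start[i] + seg_len, length.out = 11)
    w[i] <- mean(prof(tt))
  }
  w
}

#' Simulate a multi-day Holter recording at 10-s segment resolution
#'
#' Produces the quantities the segmentation and median-beat layers would
#' extract from a waveform — per-10-s interval medians, per-5-min SDNN,
#' usability flags, and per-segment/lead ST and T-wave deviation series —
#' directly from the patient's statistical models, together with ground
#' truth for every injected episode, artifact burst and gap.  This tier
#' shares its circadian, episode, symptom and noise models with
#' [generate_recording()] and exists so cohort-scale recovery experiments
#' stay tractable.
#'
#' @param spec a [patient_spec()].
#' @param days duration in days (default `spec$days`).
#' @param patient_id identifier carried into outputs.
#' @return A list of class `"holter_segments"` with elements
#'   `interval_series`, `sdnn_series`, `deviations` (a
#'   [deviation_series()]), `usable_duration` (s), `start_time`, `span_s`,
#'   `patient_id`, and `truth` (episodes, artifacts, gaps, burden state).
#' @export
simulate_segments <- function(spec, days = spec$days, patient_id = "P001") {
  stopifnot(inherits(spec, "patient_spec"))
  set.seed(spec$seed)
  span_s <- round(days * 86400)
  S <- span_s %/% SEG_LEN
  seg_start <- (seq_len(S) - 1) * SEG_LEN
  mid <- seg_start + SEG_LEN / 2

  gaps <- gap_schedule(spec, span_s)
  arts <- artifact_schedule(spec, span_s)
  in_gap <- segments_overlapping(seg_start, SEG_LEN, gaps)
  in_art <- segments_overlapping(seg_start, SEG_LEN, arts)
  usable <- !in_gap & !in_art

  hr <- circadian_hr(spec, mid) + ar1_noise(S, spec$hr_window_sd, 0.8)
  hr <- pmax(35, pmin(190, hr))
  rr <- 60000 / hr
  pq <- circadian_pq(spec, mid) + stats::rnorm(S, 0, 2)
  qrs <- spec$qrs_ms + stats::rnorm(S, 0, 1.5)
  qt <- circadian_qt(spec, mid, rr) + stats::rnorm(S, 0, 3)
  nb <- pmax(0L, as.integer(round(SEG_LEN * hr / 60 + stats::rnorm(S, 0, 0.3))))

  iv <- data.frame(window_start = seg_start, hr_bpm = hr, pq_ms = pq,
                   qrs_ms = qrs, qt_ms = qt, n_beats = nb, usable = usable)
  iv[!usable, c("hr_bpm", "pq_ms", "qrs_ms", "qt_ms")] <- NA_real_

  # SDNN per 5-min window: sampling distribution of an SD with ~nn beats
  W <- span_s %/% 300
  w_start <- (seq_len(W) - 1) * 300
  w_mid <- w_start + 150
  nn <- pmax(2L, as.integer(round(300 * circadian_hr(spec, w_mid) / 60)))
  sdnn <- spec$rr_jitter_sd * sqrt(stats::rchisq(W, nn - 1) / (nn - 1))
  w_seg_usable <- vapply(seq_len(W), function(k) {
    i <- which(seg_start >= w_start[k] & seg_start < w_start[k] + 300)
    mean(usable[i])
  }, numeric(1))
  sdnn[w_seg_usable < 0.5] <- NA_real_
  nn[w_seg_usable < 0.5] <- 0L
  sd_df <- data.frame(window_start = w_start, sdnn_ms = sdnn, nn_count = nn)

  # deviation noise: shared-across-leads component plus per-lead AR(1)
  L <- length(HOLTER_LEADS)
  mk_noise <- function() {
    shared <- ar1_noise(S, spec$dev_noise_sd * 0.5, spec$dev_noise_rho)
    idio <- vapply(seq_len(L), function(j)
      ar1_noise(S, spec$dev_noise_sd * sqrt(0.75), spec$dev_noise_rho),
      numeric(S))
    shared + idio
  }
  st <- mk_noise(); tmin <- mk_noise(); tmax <- mk_noise()

  # episode schedule
  burden_state <- stats::rbinom(1, 1, spec$p_burden)
  n_ep <- as.integer(round(spec$episode_rate * days))
  eps <- NULL
  if (n_ep > 0) {
    for (k in seq_len(n_ep)) {
      dur <- stats::runif(1, spec$episode_dur_range[1], spec$episode_dur_range[2])
      st0 <- NA_real_
      for (try in 1:25) {
        cand <- stats::runif(1, 0, span_s - dur)
        if (!any(cand < gaps$end & cand + dur > gaps$start)) { st0 <- cand; break }
      }
      if (is.na(st0)) next
      amp <- if (burden_state == 1) {
        a <- stats::rnorm(1, spec$episode_amp_mean, spec$episode_amp_sd)
        max(a, spec$episode_amp_min)
      } else spec$episode_sub_amp
      leads <- sample_contiguous_leads()
      w <- episode_segment_weights(seg_start, SEG_LEN, st0, st0 + dur,
                                   spec$episode_ramp)
      j <- match(leads, HOLTER_LEADS)
      st[, j] <- st[, j] - amp * w   # ST depression is the default kind
      eps <- rbind(eps, data.frame(
        kind = "st_offset", amplitude_mv = -amp, start = st0, end = st0 + dur,
        duration_s = dur, ramp_s = spec$episode_ramp,
        leads = paste(leads, collapse = ","), stringsAsFactors = FALSE))
    }
  }
  if (is.null(eps))
    eps <- data.frame(kind = character(0), amplitude_mv = numeric(0),
                      start = numeric(0), end = numeric(0),
                      duration_s = numeric(0), ramp_s = numeric(0),
                      leads = character(0), stringsAsFactors = FALSE)

  dev <- deviation_series(seg_start, st, tmin, tmax, usable,
                          start_time = spec$start_time)
  truth <- list(burden_state = burden_state, episodes = eps,
                artifacts = arts, gaps = gaps, span_s = span_s)
  structure(list(patient_id = patient_id, spec = spec,
                 start_time = spec$start_time, span_s = span_s,
                 interval_series = iv, sdnn_series = sd_df,
                 deviations = dev,
                 usable_duration = SEG_LEN * sum(usable),
                 truth = truth),
            class = "holter_segments")
}

#' Generate the symptom log for a simulated patient
#'
#' Background symptoms arrive as a Poisson process at `spec$symptom_rate`
#' merged symptoms per day; each injected episode additionally emits an
#' acute symptom within +/-30 min of its onset with probability
#' `spec$p_sympt_episode`.  Every merged symptom is then reported in the
#' event diary and/or as a device button press according to the reporting
#' probabilities; the two streams carry slightly offset timestamps, as on a
#' real device.
#'
#' @param spec a [patient_spec()].
#' @param truth ground truth from [simulate_segments()] or
#'   [generate_recording()] (element `truth`).
#' @param patient_id identifier for the log rows.
#' @return A data.frame with columns `patient_id`, `source`
#'   (diary/button), `timestamp` (POSIXct UTC), `type`, `duration_min`
#'   (diary rows only), plus the hidden merged-event id `event_id`.
#' @export
generate_symptom_log <- function(spec, truth, patient_id = "P001") {
  set.seed(spec$seed + 1L)
  span_s <- truth$span_s
  days <- span_s / 86400
  n_bg <- stats::rpois(1, spec$symptom_rate * days)
  t_bg <- sort(stats::runif(n_bg, 0, span_s))
  type_bg <- sample(SYMPTOM_TYPES, n_bg, replace = TRUE,
                    prob = c(0.4, 0.3, 0.2, 0.1))
  t_ep <- numeric(0); type_ep <- character(0)
  if (nrow(truth$episodes) > 0) {
    hit <- stats::runif(nrow(truth$episodes)) < spec$p_sympt_episode
    if (any(hit)) {
      t_ep <- truth$episodes$start[hit] + stats::runif(sum(hit), -10, 20) * 60
      t_ep <- pmin(pmax(t_ep, 0), span_s)
      type_ep <- sample(c("chest_pain", "dyspnea"), length(t_ep),
                        replace = TRUE, prob = c(0.7, 0.3))
    }
  }
  t_all <- c(t_bg, t_ep); type_all <- c(type_bg, type_ep)
  o <- order(t_all); t_all <- t_all[o]; type_all <- type_all[o]
  n <- length(t_all)
  if (n == 0)
    return(data.frame(patient_id = character(0), source = character(0),
                      timestamp = as.POSIXct(character(0), tz = "UTC"),
                      type = character(0), duration_min = numeric(0),
                      event_id = integer(0), stringsAsFactors = FALSE))
  # stream assignment: both / diary-only / button-only / unreported
  u <- stats::runif(n)
  p_do <- spec$p_diary - spec$p_both
  p_bo <- spec$p_button - spec$p_both
  stream <- ifelse(u < spec$p_both, "both",
            ifelse(u < spec$p_both + p_do, "diary",
            ifelse(u < spec$p_both + p_do + p_bo, "button", "none")))
  rows <- list()
  for (i in seq_len(n)) {
    if (stream[i] %in% c("both", "diary"))
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = patient_id, source = "diary",
        timestamp = spec$start_time + t_all[i] + stats::runif(1, 0, 300),
        type = type_all[i], duration_min = round(stats::runif(1, 2, 30)),
        event_id = i, stringsAsFactors = FALSE)
    if (stream[i] %in% c("both", "button"))
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = patient_id, source = "button",
        timestamp = spec$start_time + t_all[i],
        type = type_all[i], duration_min = NA_real_,
        event_id = i, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out[order(out$timestamp), , drop = FALSE]
}

#' Generate a two-group synthetic Holter cohort
#'
#' Per-patient seeds are derived deterministically from the master seed, so
#' a cohort is reproducible as a whole while every patient remains
#' individually reproducible.
#'
#' @param n_cas,n_nocas patients per group (>= 1).
#' @param cas_spec,nocas_spec group-level [patient_spec()]s; defaults from
#'   [cohort_defaults()].
#' @param seed master seed.
#' @param days recording days per patient.
#' @param level `"segments"` (default, tractable at cohort scale) or
#'   `"waveform"` (full 200 Hz signal via [generate_recording()]).
#' @param duration_s waveform duration per patient when
#'   `level = "waveform"`.
#' @param symptom_logs also generate per-patient symptom logs.
#' @return A list of class `"holter_cohort"`: `patients` (list with
#'   elements `data`, `log`, `label`, `truth`, `patient_id`), `labels`.
#' @export
generate_cohort <- function(n_cas, n_nocas,
                            cas_spec = cohort_defaults("CAS"),
                            nocas_spec = cohort_defaults("noCAS"),
                            seed = 1L, days = 3,
                            level = c("segments", "waveform"),
                            duration_s = 600,
                            symptom_logs = TRUE) {
  patients <- cohort_map(n_cas, n_nocas, identity, cas_spec, nocas_spec,
                         seed = seed, days = days, level = level,
                         duration_s = duration_s,
                         symptom_logs = symptom_logs)
  structure(list(patients = patients,
                 labels = c(rep("CAS", n_cas), rep("noCAS", n_nocas)),
                 n_cas = n_cas, n_nocas = n_nocas, seed = seed),
            class = "holter_cohort")
}

#' Stream a function over a synthetic cohort without retaining it
#'
#' Simulates the same cohort as [generate_cohort()] (identical per-patient
#' seeds and data) but applies `fun` to each patient as it is generated and
#' keeps only the result — the memory-bounded route for cohorts of
#' hundreds or thousands of multi-day patients.
#'
#' @inheritParams generate_cohort
#' @param fun function of one patient (a list with `patient_id`, `label`,
#'   `data`, `log`, `truth`).
#' @return list of `fun` results, one per patient, CAS patients first.
#' @export
cohort_map <- function(n_cas, n_nocas, fun,
                       cas_spec = cohort_defaults("CAS"),
                       nocas_spec = cohort_defaults("noCAS"),
                       seed = 1L, days = 3,
                       level = c("segments", "waveform"),
                       duration_s = 600, symptom_logs = TRUE) {
  stopifnot(n_cas >= 1, n_nocas >= 1)
  level <- match.arg(level)
  n <- n_cas + n_nocas
  labels <- c(rep("CAS", n_cas), rep("noCAS", n_nocas))
  seeds <- (as.integer(seed) + 7919L * seq_len(n)) %% 2147483562L
  out <- vector("list", n)
  for (i in seq_len(n)) {
    spec <- if (labels[i] == "CAS") cas_spec else nocas_spec
    spec$seed <- seeds[i]
    pid <- sprintf("P%03d", i)
    if (level == "segments") {
      dat <- simulate_segments(spec, days = days, patient_id = pid)
    } else {
      dat <- generate_recording(spec, duration_s = duration_s,
                                patient_id = pid)
    }
    truth <- dat$truth
    log <- if (symptom_logs) generate_symptom_log(spec, truth, pid) else NULL
    out[[i]] <- fun(list(patient_id = pid, label = labels[i],
                         data = dat, log = log, truth = truth))
  }
  out
}
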