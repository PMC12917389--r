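# Waveform-level synthetic tier: full 200 Hz 12-lead signal built from the
# parametric beat template, with circadian RR/PQ/QT modulation, injected
# ST/T episodes, baseline wander, artifact bursts and annotated gaps.

#' Specify one injected ischemia-like episode
#'
#' @param kind `"st_offset"` (additive ST-segment shift) or `"t_scale"`
#'   (additive change of T-wave peak amplitude).
#' @param amplitude_mv signed amplitude in mV as it should appear in the
#'   affected lead (negative = depression).
#' @param leads character vector of affected leads (subset of
#'   [HOLTER_LEADS]).
#' @param start,duration_s episode start (s since recording start) and
#'   duration (s).
#' @param ramp_s onset/offset amplitude ramp (s).
#' @return list of class `"episode_spec"`.
#' @export
episode_spec <- function(kind = c("st_offset", "t_scale"), amplitude_mv,
                         leads, start, duration_s, ramp_s = 10) {
  kind <- match.arg(kind)
  if (duration_s <= 0) stop("episode duration must be positive")
  if (length(leads) == 0) stop("episode lead set must be non-empty")
  bad <- setdiff(leads, HOLTER_LEADS)
  if (length(bad)) stop("unknown lead name(s): ", paste(bad, collapse = ", "))
  structure(list(kind = kind, amplitude_mv = amplitude_mv, leads = leads,
                 start = start, duration_s = duration_s, ramp_s = ramp_s),
            class = "episode_spec")
}

# time-ramp factor of an episode at times t (s)
episode_ramp_factor <- function(ep, t) {
  f <- pmin(1, pmax(0, (t - ep$start) / max(ep$ramp_s, 1e-9)))
  g <- pmin(1, pmax(0, (ep$start + ep$duration_s - t) / max(ep$ramp_s, 1e-9)))
  pmin(f, g) * (t >= ep$start & t <= ep$start + ep$duration_s)
}

#' Construct an ECG recording container
#'
#' @param signal samples x leads matrix (mV).
#' @param fs sampling rate (Hz).
#' @param start_time POSIXct start.
#' @param leads channel labels.
#' @param gaps data.frame(start, end) of zero-filled spans (s), half-open.
#' @param patient_id identifier.
#' @return list of class `"ecg_recording"`.
#' @export
ecg_recording <- function(signal, fs, start_time, leads = HOLTER_LEADS,
                          gaps = data.frame(start = numeric(0),
                                            end = numeric(0)),
                          patient_id = "P001") {
  stopifnot(fs > 0, is.matrix(signal), ncol(signal) == length(leads))
  bad <- setdiff(leads, HOLTER_LEADS)
  if (length(bad)) stop("unknown lead name(s): ", paste(bad, collapse = ", "))
  span <- nrow(signal) / fs
  if (nrow(gaps)) {
    if (any(gaps$start < 0 | gaps$end > span + 1e-9 | gaps$end <= gaps$start))
      stop("gap intervals must lie within the record span")
    o <- order(gaps$start)
    gaps <- gaps[o, , drop = FALSE]
    if (nrow(gaps) > 1 && any(gaps$start[-1] < gaps$end[-nrow(gaps)]))
      stop("gap intervals must not overlap")
  }
  colnames(signal) <- leads
  structure(list(signal = signal, fs = fs, start_time = start_time,
                 leads = leads, gaps = gaps, patient_id = patient_id,
                 span_s = span),
            class = "ecg_recording")
}

#' @export
print.ecg_recording <- function(x, ...) {
  cat(sprintf("<ecg_recording> %s: %d leads, %.0f Hz, %.1f min, %d gap(s)\n",
              x$patient_id, length(x$leads), x$fs, x$span_s / 60,
              nrow(x$gaps)))
  invisible(x)
}

#' Generate a synthetic 12-lead Holter waveform with ground truth
#'
#' Beat-to-beat RR follows the circadian heart-rate cosine plus white RR
#' jitter; per-beat PQ and QT follow their circadian models (QT through the
#' Bazett relation); each beat is rendered from the compact-support
#' template, projected onto the 12 leads, and injected episodes shift the
#' ST segment (or T amplitude) of the affected leads by the specified
#' amount.  Gaps are zero-filled and annotated; artifact bursts add
#' high-amplitude noise and are recorded in the truth.
#'
#' @param spec a [patient_spec()].
#' @param duration_s recording length in seconds (default the full
#'   `spec$days`; waveform memory grows at about 70 MB per hour).
#' @param episodes optional list of [episode_spec()]s; `NULL` draws a
#'   schedule from the spec's episode model.
#' @param patient_id identifier.
#' @return list with `recording` (an [ecg_recording()]) and `truth`
#'   (beats, episodes, artifacts, gaps, span_s, burden_state).
#' @export
generate_recording <- function(spec, duration_s = spec$days * 86400,
                               episodes = NULL, patient_id = "P001") {
  stopifnot(inherits(spec, "patient_spec"))
  if (duration_s <= 0) stop("duration must be positive")
  set.seed(spec$seed)
  fs <- 200
  span <- duration_s
  n_samp <- round(span * fs)

  # --- beat train ---------------------------------------------------------
  b <- numeric(0); t <- 0.5   # first QRS onset 0.5 s in
  est <- ceiling(span / (60 / (spec$hr_mesor + spec$hr_amp))) + 16
  b <- numeric(est); rrs <- numeric(est); i <- 0
  while (t < span - 1) {
    i <- i + 1
    hr <- max(30, circadian_hr(spec, t))
    rr <- 60 / hr + stats::rnorm(1, 0, spec$rr_jitter_sd / 1000)
    rr <- min(max(rr, 0.33), 2)
    b[i] <- t; rrs[i] <- rr * 1000
    t <- t + rr
  }
  b <- b[seq_len(i)]; rrs <- rrs[seq_len(i)]
  n_beat <- length(b)
  ect <- stats::runif(n_beat) < spec$ectopic_rate
  ect[1] <- FALSE
  b[ect] <- b[ect] - 0.25 * rrs[ect] / 1000   # premature

  bj <- spec$beat_jitter
  pq <- circadian_pq(spec, b) + stats::rnorm(n_beat, 0, 2 * bj)
  qrs <- spec$qrs_ms + stats::rnorm(n_beat, 0, 1.5 * bj)
  qt <- circadian_qt(spec, b, rrs) + stats::rnorm(n_beat, 0, 3 * bj)
  qrs[ect] <- 140
  rr_prev <- c(NA, diff(b) * 1000)

  # --- episode schedule ---------------------------------------------------
  gaps <- gap_schedule(spec, span)
  burden_state <- stats::rbinom(1, 1, spec$p_burden)
  if (is.null(episodes)) {
    episodes <- list()
    n_ep <- as.integer(round(spec$episode_rate * span / 86400))
    for (k in seq_len(n_ep)) {
      dur <- stats::runif(1, spec$episode_dur_range[1],
                          spec$episode_dur_range[2])
      if (dur >= span - 2) next
      st0 <- stats::runif(1, 0, span - dur)
      amp <- if (burden_state == 1)
        -max(stats::rnorm(1, spec$episode_amp_mean, spec$episode_amp_sd),
             spec$episode_amp_min)
      else -spec$episode_sub_amp
      episodes[[length(episodes) + 1L]] <-
        episode_spec("st_offset", amp, sample_contiguous_leads(), st0, dur,
                     spec$episode_ramp)
    }
  } else {
    lapply(episodes, function(e) stopifnot(inherits(e, "episode_spec")))
  }

  # --- waveform assembly --------------------------------------------------
  scales <- default_lead_scales()
  sig <- matrix(0, n_samp, 12)
  t_dur <- 160
  for (k in seq_len(n_beat)) {
    p_amp_k <- if (ect[k]) 0 else 0.12
    lo_ms <- -pq[k] - 40; hi_ms <- qt[k] + 40
    i0 <- floor((b[k] + lo_ms / 1000) * fs) + 1L
    i1 <- ceiling((b[k] + hi_ms / 1000) * fs) + 1L
    i0 <- max(i0, 1L); i1 <- min(i1, n_samp)
    if (i1 <= i0) next
    idx <- i0:i1
    t_ms <- ((idx - 1) / fs - b[k]) * 1000
    unit <- beat_wave(t_ms, pq = pq[k], qrs = qrs[k], qt = qt[k],
                      p_amp = p_amp_k,
                      r_amp = if (ect[k]) 1.2 else 1.0)
    sig[idx, ] <- sig[idx, ] + outer(unit, scales)
    # episode injection on this beat's ST segment / T wave
    for (ep in episodes) {
      if (b[k] + qt[k] / 1000 < ep$start ||
          b[k] > ep$start + ep$duration_s) next
      f <- episode_ramp_factor(ep, b[k])
      if (f <= 0) next
      j <- match(ep$leads, HOLTER_LEADS)
      if (ep$kind == "st_offset") {
        st_lo <- qrs[k]; st_hi <- max(qt[k] - t_dur, qrs[k] + 100)
        w <- numeric(length(t_ms))
        inw <- t_ms >= st_lo & t_ms <= st_hi
        # 10 ms cosine edges inside the ST window
        edge <- 10
        u <- pmin(1, pmax(0, (t_ms - st_lo) / edge))
        v <- pmin(1, pmax(0, (st_hi - t_ms) / edge))
        w[inw] <- (pmin(u, v) * inw)[inw]
        sig[idx, j] <- sig[idx, j] + ep$amplitude_mv * f * w
      } else {
        tl <- numeric(length(t_ms))
        inr <- t_ms >= qt[k] - t_dur & t_ms <= qt[k]
        tl[inr] <- 0.5 * (1 - cos(2 * pi * (t_ms[inr] - qt[k] + t_dur) / t_dur))
        sig[idx, j] <- sig[idx, j] + ep$amplitude_mv * f * tl
      }
    }
  }

  # --- noise, wander, artifacts, gaps ------------------------------------
  if (spec$noise_sd > 0)
    sig <- sig + matrix(stats::rnorm(n_samp * 12, 0, spec$noise_sd),
                        n_samp, 12)
  if (spec$wander_amp > 0) {
    ts <- (seq_len(n_samp) - 1) / fs
    for (j in 1:12) {
      ph <- stats::runif(2, 0, 2 * pi)
      sig[, j] <- sig[, j] +
        spec$wander_amp * sin(2 * pi * 0.25 * ts + ph[1]) +
        0.5 * spec$wander_amp * sin(2 * pi * 0.05 * ts + ph[2])
    }
  }
  arts <- artifact_schedule(spec, span, mean_dur = 30)
  if (nrow(arts)) for (k in seq_len(nrow(arts))) {
    ai <- max(1L, floor(arts$start[k] * fs)):min(n_samp, ceiling(arts$end[k] * fs))
    sig[ai, ] <- sig[ai, ] + matrix(stats::rnorm(length(ai) * 12, 0, 0.8),
                                    length(ai), 12)
  }
  gaps <- gaps[gaps$start < span, , drop = FALSE]
  if (nrow(gaps)) for (k in seq_len(nrow(gaps))) {
    gi <- max(1L, floor(gaps$start[k] * fs) + 1L):min(n_samp, ceiling(gaps$end[k] * fs))
    sig[gi, ] <- 0
  }

  ep_df <- if (length(episodes)) do.call(rbind, lapply(episodes, function(e)
    data.frame(kind = e$kind, amplitude_mv = e$amplitude_mv,
               start = e$start, end = e$start + e$duration_s,
               duration_s = e$duration_s, ramp_s = e$ramp_s,
               leads = paste(e$leads, collapse = ","),
               stringsAsFactors = FALSE)))
  else data.frame(kind = character(0), amplitude_mv = numeric(0),
                  start = numeric(0), end = numeric(0),
                  duration_s = numeric(0), ramp_s = numeric(0),
                  leads = character(0), stringsAsFactors = FALSE)

  beats_truth <- data.frame(
    qrs_on = b, r_peak = b + r_peak_offset(qrs) / 1000,
    class = ifelse(ect, "non-sinus", "sinus"),
    pq_ms = ifelse(ect, NA, pq), qrs_ms = qrs, qt_ms = qt, rr_ms = rr_prev)

  rec <- ecg_recording(sig, fs, spec$start_time, gaps = gaps,
                       patient_id = patient_id)
  truth <- list(beats = beats_truth, episodes = ep_df, artifacts = arts,
                gaps = gaps, span_s = span, burden_state = burden_state)
  list(recording = rec, truth = truth)
}
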