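#' Parametric single-beat morphology
#'
#' The beat model is a sum of compact-support raised-cosine lobes (P, Q, R,
#' S, T) on a 0 mV isoelectric line, with every wave supported exactly
#' between its nominal onset and offset.  Fiducial times are therefore exact
#' model quantities, which makes delineation accuracy measurable against
#' ground truth.  Times are in ms relative to QRS onset.
#'
#' @param t_ms numeric vector of times (ms) relative to QRS onset.
#' @param pq PQ interval (P onset to QRS onset), ms.
#' @param qrs QRS duration, ms.
#' @param qt QT interval (QRS onset to T offset), ms.
#' @param p_dur,p_amp P-wave duration (ms) and peak amplitude (mV).
#' @param q_amp,r_amp,s_amp Q/R/S lobe peak amplitudes (mV).
#' @param t_dur,t_amp T-wave duration (ms) and peak amplitude (mV).
#' @return numeric vector of amplitudes (mV), same length as `t_ms`.
#' @export
beat_wave <- function(t_ms, pq = 160, qrs = 92, qt = 400,
                      p_dur = 100, p_amp = 0.12,
                      q_amp = -0.10, r_amp = 1.0, s_amp = -0.20,
                      t_dur = 160, t_amp = 0.30) {
  lobe <- function(t, a, b, amp) {
    v <- numeric(length(t))
    i <- t >= a & t <= b
    v[i] <- amp * 0.5 * (1 - cos(2 * pi * (t[i] - a) / (b - a)))
    v
  }
  v <- lobe(t_ms, -pq, -pq + p_dur, p_amp)
  v <- v + lobe(t_ms, 0.00 * qrs, 0.25 * qrs, q_amp)
  v <- v + lobe(t_ms, 0.15 * qrs, 0.60 * qrs, r_amp)
  v <- v + lobe(t_ms, 0.55 * qrs, 1.00 * qrs, s_amp)
  v <- v + lobe(t_ms, qt - t_dur, qt, t_amp)
  v
}

# Nominal R-peak time (ms after QRS onset) of beat_wave
r_peak_offset <- function(qrs = 92) 0.375 * qrs

#' Default per-lead projection weights for the 12 standard leads
#'
#' One multiplicative scale per lead applied to the whole template; signs
#' follow the usual lead polarities (aVR and V1 predominantly negative).
#' @return named numeric vector over [HOLTER_LEADS].
#' @export
default_lead_scales <- function() {
  c(I = 0.55, II = 1.00, III = 0.45, aVR = -0.75, aVL = 0.25, aVF = 0.70,
    V1 = -0.50, V2 = 0.90, V3 = 1.10, V4 = 1.20, V5 = 1.00, V6 = 0.80)
}

#' Sampled single-beat template with its fiducial offsets
#'
#' @param fs sampling rate (Hz).
#' @param pq,qrs,qt intervals in ms (see [beat_wave()]).
#' @param lead_scales named per-lead scales; default [default_lead_scales()].
#' @param ... further shape arguments passed to [beat_wave()].
#' @return A list of class `"morphology_template"` with `wave` (samples x
#'   leads matrix, mV), `t_ms` (times relative to QRS onset), and
#'   `fiducials_ms` (named: p_on, p_off, qrs_on, qrs_off, t_off, r_peak,
#'   j_point).  The J point is identified with QRS offset.
#' @export
morphology_template <- function(fs = 200, pq = 160, qrs = 92, qt = 400,
                                lead_scales = default_lead_scales(), ...) {
  dots <- list(...)
  p_dur <- if (!is.null(dots$p_dur)) dots$p_dur else 100
  fid <- c(p_on = -pq, p_off = -pq + p_dur, qrs_on = 0, qrs_off = qrs,
           t_off = qt, r_peak = r_peak_offset(qrs), j_point = qrs)
  ord <- fid[c("p_on", "p_off", "qrs_on", "qrs_off", "t_off")]
  if (any(diff(ord) < 0)) stop("fiducial offsets must be non-decreasing")
  t_ms <- seq(-pq - 40, qt + 40, by = 1000 / fs)
  unit <- beat_wave(t_ms, pq = pq, qrs = qrs, qt = qt, ...)
  wave <- outer(unit, lead_scales)
  colnames(wave) <- names(lead_scales)
  if (max(abs(wave)) > 5) stop("template amplitude exceeds 5 mV")
  iso <- t_ms >= fid["p_off"] & t_ms <= fid["qrs_on"]
  if (any(iso) && max(abs(unit[iso])) > 1e-9)
    stop("PQ baseline segment is not isoelectric")
  structure(list(wave = wave, t_ms = t_ms, fiducials_ms = fid,
                 fs = fs, pq = pq, qrs = qrs, qt = qt),
            class = "morphology_template")
}
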