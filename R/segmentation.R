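# Open-stack beat detection and delineation: a difference-filter QRS
# detector plus threshold/derivative delineation on lead II, replacing the
# proprietary analyzer whose outputs the downstream layers consume.
# Conformance is defined by parameter recovery against synthetic truth.

moving_mean <- function(x, w) {
  as.numeric(stats::filter(x, rep(1 / w, w), sides = 2))
}

# gap mask per sample
sample_in_gap <- function(n, fs, gaps) {
  m <- logical(n)
  if (nrow(gaps)) for (k in seq_len(nrow(gaps))) {
    i0 <- max(1L, floor(gaps$start[k] * fs) + 1L)
    i1 <- min(n, ceiling(gaps$end[k] * fs))
    if (i1 >= i0) m[i0:i1] <- TRUE
  }
  m
}

#' Detect QRS complexes (R peaks)
#'
#' Difference filter, squaring, 150-ms moving-window integration and an
#' adaptive threshold on lead II (or the lead with the largest amplitude
#' range if II is absent), with a 250-ms refractory rule and R-peak
#' refinement on the raw signal.
#'
#' @param recording an [ecg_recording()].
#' @return data.frame with `r_peak` (s) and `r_idx` (sample index), empty
#'   (with a warning) on flatline or all-gap input.
#' @export
detect_beats <- function(recording) {
  stopifnot(inherits(recording, "ecg_recording"))
  fs <- recording$fs
  n <- nrow(recording$signal)
  gapm <- sample_in_gap(n, fs, recording$gaps)
  if (sum(!gapm) < 30 * fs)
    stop("need at least 30 s of non-gap signal")
  lead <- if ("II" %in% recording$leads) "II" else
    recording$leads[which.max(apply(recording$signal, 2, function(v)
      diff(range(v))))]
  x <- recording$signal[, lead]
  d <- c(0, diff(x))
  d[gapm] <- 0
  integ <- moving_mean(d^2, max(3L, round(0.15 * fs)))
  integ[is.na(integ)] <- 0
  thr <- 0.2 * stats::quantile(integ[!gapm], 0.98, names = FALSE)
  if (!is.finite(thr) || thr <= 1e-12) {
    warning("flatline or all-gap input: no beats detected")
    return(data.frame(r_peak = numeric(0), r_idx = integer(0)))
  }
  above <- integ > thr & !gapm
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  reg <- cbind(starts[r$values], ends[r$values])
  if (nrow(reg) == 0) {
    warning("no beats detected")
    return(data.frame(r_peak = numeric(0), r_idx = integer(0)))
  }
  cand <- integer(nrow(reg))
  for (k in seq_len(nrow(reg))) {
    i0 <- reg[k, 1]; i1 <- reg[k, 2]
    cand[k] <- i0 - 1L + which.max(integ[i0:i1])
  }
  # refine to raw R peak within +/-60 ms
  w <- round(0.06 * fs)
  for (k in seq_along(cand)) {
    i0 <- max(1L, cand[k] - w); i1 <- min(n, cand[k] + w)
    cand[k] <- i0 - 1L + which.max(x[i0:i1])
  }
  cand <- unique(cand)
  # greedy refractory: keep larger integration height within 250 ms
  o <- order(integ[cand], decreasing = TRUE)
  keep <- logical(length(cand))
  acc <- numeric(0)
  for (k in o) {
    if (!length(acc) || min(abs(acc - cand[k])) > 0.25 * fs) {
      keep[k] <- TRUE
      acc <- c(acc, cand[k])
    }
  }
  idx <- sort(cand[keep])
  data.frame(r_peak = (idx - 1) / fs, r_idx = idx)
}

# threshold crossing helpers on one beat neighbourhood -----------------

# scan backward from `from` while |x - b0| stays above thr; return first
# index (towards lo) where it is below thr for `hold` consecutive samples
scan_boundary <- function(x, b0, from, to, thr, hold = 3L) {
  step <- if (to < from) -1L else 1L
  run <- 0L
  for (i in seq(from, to, by = step)) {
    if (abs(x[i] - b0) < thr) {
      run <- run + 1L
      if (run >= hold) return(i - step * (hold - 1L))
    } else run <- 0L
  }
  NA_integer_
}

#' Delineate detected beats and measure conduction intervals
#'
#' For each R peak: local pre-P baseline, QRS onset/offset by amplitude
#' threshold on the raw lead II signal, P-wave and T-wave boundaries by a
#' 2.5% amplitude threshold on a 25-ms smoothed signal.  Beats whose
#' fiducials cannot be resolved in physiologic order are flagged
#' `artifact`; beats without a detectable P wave keep a null PQ.
#' Classification: `non-sinus` when QRS exceeds 120 ms or RR deviates more
#' than 20% from the local median RR.
#'
#' @param recording an [ecg_recording()].
#' @param beats output of [detect_beats()].
#' @return data.frame, one row per beat: `r_peak`, `class`, fiducial times
#'   (s): `p_on`, `p_off`, `qrs_on`, `qrs_off`, `t_off`; intervals `pq_ms`,
#'   `qrs_ms`, `qt_ms`, `rr_ms` (to the previous sinus beat, `NA` when that
#'   beat is not sinus).
#' @export
delineate <- function(recording, beats) {
  fs <- recording$fs
  n <- nrow(recording$signal)
  lead <- if ("II" %in% recording$leads) "II" else recording$leads[1]
  x <- recording$signal[, lead]
  # remove baseline wander with a 0.6-s running-median filter
  k <- round(0.6 * fs); if (k %% 2 == 0) k <- k + 1L
  x <- x - stats::runmed(x, k, endrule = "constant")
  sm <- moving_mean(x, max(3L, round(0.025 * fs)))
  sm[is.na(sm)] <- x[is.na(sm)]
  nb <- nrow(beats)
  out <- data.frame(r_peak = beats$r_peak, class = rep("sinus", nb),
                    p_on = NA_real_, p_off = NA_real_, qrs_on = NA_real_,
                    qrs_off = NA_real_, t_off = NA_real_,
                    pq_ms = NA_real_, qrs_ms = NA_real_, qt_ms = NA_real_,
                    rr_ms = NA_real_, stringsAsFactors = FALSE)
  if (nb == 0) return(out)
  ms <- function(k) max(1L, round(k * fs / 1000))
  for (k in seq_len(nb)) {
    r <- beats$r_idx[k]
    b_lo <- max(1L, r - ms(320)); b_hi <- max(1L, r - ms(240))
    b0 <- stats::median(x[b_lo:b_hi])
    ra <- x[r] - b0
    if (!is.finite(ra) || abs(ra) < 0.1) { out$class[k] <- "artifact"; next }
    qon <- scan_boundary(x, b0, max(1L, r - ms(20)), max(1L, r - ms(130)),
                         0.02 * abs(ra))
    qoff <- scan_boundary(x, b0, min(n, r + ms(20)), min(n, r + ms(150)),
                          0.05 * abs(ra))
    if (is.na(qon) || is.na(qoff)) { out$class[k] <- "artifact"; next }
    # P wave in [qon - 240 ms, qon - 10 ms]
    p_lo <- max(1L, qon - ms(240)); p_hi <- max(1L, qon - ms(10))
    pw <- sm[p_lo:p_hi] - b0
    pk <- p_lo - 1L + which.max(abs(pw))
    p_amp <- sm[pk] - b0
    p_on <- p_off <- NA_integer_
    if (abs(p_amp) >= 0.03) {
      pthr <- max(0.025 * abs(p_amp), 0.008)
      p_on <- scan_boundary(sm, b0, pk, p_lo, pthr, hold = 2L)
      p_off <- scan_boundary(sm, b0, pk, min(pk + ms(150), qon), pthr,
                             hold = 2L)
      if (is.na(p_on) || is.na(p_off)) { p_on <- p_off <- NA_integer_ }
    }
    # T wave after QRS offset
    t_lo <- min(n, qoff + ms(60))
    rr_next <- if (k < nb) (beats$r_idx[k + 1] - r) / fs else 0.8
    t_hi <- min(n, qoff + ms(min(480, max(200, 0.65 * rr_next * 1000))))
    t_off <- NA_integer_
    if (t_hi > t_lo + 4) {
      tw <- sm[t_lo:t_hi] - b0
      tk <- t_lo - 1L + which.max(abs(tw))
      t_amp <- sm[tk] - b0
      if (abs(t_amp) >= 0.05) {
        tthr <- max(0.025 * abs(t_amp), 0.008)
        t_off <- scan_boundary(sm, b0, tk, t_hi, tthr, hold = 2L)
      }
    }
    fid <- c(p_on, p_off, qon, qoff, t_off)
    fid_def <- fid[!is.na(fid)]
    if (any(diff(fid_def) < 0)) { out$class[k] <- "artifact"; next }
    out$p_on[k] <- (p_on - 1) / fs
    out$p_off[k] <- (p_off - 1) / fs
    out$qrs_on[k] <- (qon - 1) / fs
    out$qrs_off[k] <- (qoff - 1) / fs
    out$t_off[k] <- (t_off - 1) / fs
    out$pq_ms[k] <- if (!is.na(p_on)) (qon - p_on) * 1000 / fs else NA_real_
    out$qrs_ms[k] <- (qoff - qon) * 1000 / fs
    out$qt_ms[k] <- if (!is.na(t_off)) (t_off - qon) * 1000 / fs else NA_real_
  }
  classify_beats(out)
}

#' Classify beats as sinus / non-sinus / artifact
#'
#' Applied by [delineate()]; exported for reuse on externally produced
#' annotations.  Rules: QRS duration above 120 ms or RR deviating more than
#' 20% from the local (running, width 9) median RR marks a beat non-sinus;
#' `rr_ms` is then defined only for beats whose predecessor is sinus.
#'
#' @param ann beat annotation data.frame (see [delineate()]).
#' @return the annotated data.frame with `class` and `rr_ms` filled in.
#' @export
classify_beats <- function(ann) {
  nb <- nrow(ann)
  if (nb == 0) return(ann)
  rr_raw <- c(NA, diff(ann$r_peak) * 1000)
  loc_med <- rr_raw
  if (nb >= 3) {
    ok <- !is.na(rr_raw)
    if (sum(ok) >= 3)
      loc_med[ok] <- stats::runmed(rr_raw[ok], k = min(9L, sum(ok) -
                                                         (sum(ok) + 1) %% 2))
  }
  wide <- !is.na(ann$qrs_ms) & ann$qrs_ms > 120
  irregular <- !is.na(rr_raw) & !is.na(loc_med) &
    abs(rr_raw - loc_med) > 0.2 * loc_med
  ann$class[ann$class != "artifact" & (wide | irregular)] <- "non-sinus"
  sinus <- ann$class == "sinus"
  prev_sinus <- c(FALSE, sinus[-nb])
  ann$rr_ms <- ifelse(sinus & prev_sinus, rr_raw, NA_real_)
  ann
}

#' Per-10-s interval medians over sinus beats
#'
#' Windows are aligned to the recording clock and continuous across gaps.
#' Heart rate is `60000 / median(RR)`; medians are absent for windows with
#' fewer than 3 sinus beats or flagged unusable.
#'
#' @param beats annotated beats from [delineate()].
#' @param span_s recording span (s).
#' @param usable optional logical vector per window (from
#'   [usability_mask()]).
#' @param window window length (s).
#' @return data.frame: window_start, hr_bpm, pq_ms, qrs_ms, qt_ms, n_beats,
#'   usable.
#' @export
interval_series <- function(beats, span_s, usable = NULL, window = SEG_LEN) {
  S <- floor(span_s / window)
  ws <- (seq_len(S) - 1) * window
  out <- data.frame(window_start = ws, hr_bpm = rep(NA_real_, S),
                    pq_ms = rep(NA_real_, S), qrs_ms = rep(NA_real_, S),
                    qt_ms = rep(NA_real_, S), n_beats = rep(0L, S),
                    usable = if (is.null(usable)) rep(TRUE, S)
                             else usable[seq_len(S)])
  if (nrow(beats)) {
    wi <- floor(beats$r_peak / window) + 1L
    inr <- wi >= 1 & wi <= S
    cnt <- tabulate(wi[inr], nbins = S)
    out$n_beats <- cnt
    sin_i <- which(beats$class == "sinus" & inr)
    med_by <- function(v) {
      ok <- sin_i[!is.na(v[sin_i])]
      res <- rep(NA_real_, S)
      if (length(ok)) {
        agg <- tapply(v[ok], wi[ok], stats::median)
        res[as.integer(names(agg))] <- as.numeric(agg)
      }
      res
    }
    nsin <- tabulate(wi[sin_i], nbins = S)
    med_rr <- med_by(beats$rr_ms)
    out$hr_bpm <- 60000 / med_rr
    out$pq_ms <- med_by(beats$pq_ms)
    out$qrs_ms <- med_by(beats$qrs_ms)
    out$qt_ms <- med_by(beats$qt_ms)
    low <- nsin < 3
    out[low, c("hr_bpm", "pq_ms", "qrs_ms", "qt_ms")] <- NA_real_
    out$usable <- out$usable & !low
  } else {
    out$usable <- FALSE
  }
  out[!out$usable, c("hr_bpm", "pq_ms", "qrs_ms", "qt_ms")] <- NA_real_
  out
}

#' SDNN per 5-minute window
#'
#' SDNN is the sample standard deviation (denominator N-1) of NN
#' (sinus-to-sinus) intervals within the window; absent when fewer than 30
#' NN intervals are available.
#'
#' @param beats annotated beats.
#' @param span_s recording span (s).
#' @param window window length (s).
#' @param min_nn minimum NN count per window.
#' @return data.frame: window_start, sdnn_ms, nn_count.
#' @export
sdnn_series <- function(beats, span_s, window = 300, min_nn = 30) {
  W <- floor(span_s / window)
  ws <- (seq_len(W) - 1) * window
  out <- data.frame(window_start = ws, sdnn_ms = rep(NA_real_, W),
                    nn_count = rep(0L, W))
  nn_i <- which(beats$class == "sinus" & !is.na(beats$rr_ms))
  if (length(nn_i)) {
    wi <- floor(beats$r_peak[nn_i] / window) + 1L
    inr <- wi >= 1 & wi <= W
    nn_i <- nn_i[inr]; wi <- wi[inr]
    cnt <- tabulate(wi, nbins = W)
    out$nn_count <- cnt
    sds <- tapply(beats$rr_ms[nn_i], wi, stats::sd)
    out$sdnn_ms[as.integer(names(sds))] <- as.numeric(sds)
    out$sdnn_ms[cnt < min_nn] <- NA_real_
  }
  out
}

#' Per-10-s usability flags and usable duration
#'
#' A window is unusable iff it overlaps a gap, its artifact-beat fraction
#' exceeds `artifact_limit`, or its amplitude saturates (|v| >= 5 mV).
#'
#' @param recording an [ecg_recording()].
#' @param beats annotated beats (may be `NULL`: only gaps and saturation are
#'   then checked).
#' @param artifact_limit maximum tolerated artifact-beat fraction.
#' @param window window length (s).
#' @return list with `window_start`, `usable` (logical), and
#'   `usable_duration_s`.
#' @export
usability_mask <- function(recording, beats = NULL, artifact_limit = 0.3,
                           window = SEG_LEN) {
  fs <- recording$fs
  S <- floor(recording$span_s / window)
  ws <- (seq_len(S) - 1) * window
  usable <- !segments_overlapping(ws, window, recording$gaps)
  # amplitude saturation per window
  absmax <- apply(abs(recording$signal), 1, max)
  for (s in which(usable)) {
    i0 <- floor(ws[s] * fs) + 1L
    i1 <- min(nrow(recording$signal), floor((ws[s] + window) * fs))
    if (max(absmax[i0:i1]) >= 5) usable[s] <- FALSE
  }
  if (!is.null(beats) && nrow(beats)) {
    wi <- floor(beats$r_peak / window) + 1L
    inr <- wi >= 1 & wi <= S
    tot <- tabulate(wi[inr], nbins = S)
    art <- tabulate(wi[inr & beats$class == "artifact"], nbins = S)
    frac <- ifelse(tot > 0, art / tot, 0)
    usable <- usable & frac <= artifact_limit
  }
  list(window_start = ws, usable = usable,
       usable_duration_s = window * sum(usable))
}
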