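# Median-beat layer: per-lead median beats per 10-s segment, the patient's
# heart-rate-binned baseline library, and ST / T-wave deviations measured
# against the matched baseline.  All beats are aligned on QRS onset; the
# measurement windows are J+40..J+80 ms for the ST segment (J point = QRS
# offset) and QRS offset + 80 ms .. T offset for the T wave, both referenced
# to the PQ-segment isoelectric level (QRS onset -30..-10 ms).

MB_T_MS <- seq(-200, 450, by = 5)   # beat window at 200 Hz
ST_WIN <- c(40, 80)
ISO_WIN <- c(-30, -10)
T_START_AFTER_J <- 80
HR_BIN_BREAKS <- seq(37.5, 142.5, by = 5)   # bin centers 40, 45, ..., 140

#' Construct a median beat
#'
#' @param wave samples x leads matrix (mV), sampled on `t_ms`.
#' @param hr_bpm segment median heart rate.
#' @param qrs_off_ms,t_off_ms fiducials (ms after QRS onset) inherited from
#'   the segment's median intervals.
#' @param n_beats contributing beat count (>= 3).
#' @param t_ms sample times (ms relative to QRS onset).
#' @param segment_start segment start time (s), optional.
#' @return list of class `"median_beat"`.
#' @export
median_beat <- function(wave, hr_bpm, qrs_off_ms, t_off_ms, n_beats = 3L,
                        t_ms = MB_T_MS, segment_start = NA_real_) {
  stopifnot(is.matrix(wave), nrow(wave) == length(t_ms))
  if (t_ms[1] > -200 || t_ms[length(t_ms)] < 450)
    stop("median beat must span at least QRS onset -200 ms to +450 ms")
  if (n_beats < 3) stop("median beat requires at least 3 beats")
  structure(list(wave = wave, t_ms = t_ms, hr_bpm = hr_bpm,
                 qrs_off_ms = qrs_off_ms, t_off_ms = t_off_ms,
                 n_beats = n_beats, segment_start = segment_start),
            class = "median_beat")
}

#' Median beats per 10-s segment of a recording
#'
#' For every usable window with at least 3 delineated sinus beats, the
#' sample-wise median across QRS-onset-aligned beats, per lead.
#'
#' @param recording an [ecg_recording()].
#' @param beats annotated beats from [delineate()].
#' @param usable logical per-window usability (from [usability_mask()]);
#'   `NULL` treats all windows usable.
#' @param window window length (s).
#' @return list of class `"median_beats"`: `segments` (data.frame:
#'   segment_start, hr_bpm, n_beats, qrs_off_ms, t_off_ms, has_beat) and
#'   `beats` (list of [median_beat()] or `NULL` per segment).
#' @export
median_beats <- function(recording, beats, usable = NULL, window = SEG_LEN) {
  fs <- recording$fs
  S <- floor(recording$span_s / window)
  ws <- (seq_len(S) - 1) * window
  if (is.null(usable)) usable <- rep(TRUE, S)
  rel <- round(MB_T_MS * fs / 1000)   # sample offsets from QRS onset
  n <- nrow(recording$signal)
  seg_df <- data.frame(segment_start = ws, hr_bpm = NA_real_, n_beats = 0L,
                       qrs_off_ms = NA_real_, t_off_ms = NA_real_,
                       has_beat = FALSE)
  mb_list <- vector("list", S)
  sinus <- which(beats$class == "sinus" & !is.na(beats$qrs_on))
  if (length(sinus)) {
    wi <- floor(beats$r_peak[sinus] / window) + 1L
    for (s in which(usable[seq_len(S)])) {
      bi <- sinus[wi == s]
      if (length(bi) < 3) next
      q_idx <- round(beats$qrs_on[bi] * fs) + 1L
      ok <- q_idx + rel[1] >= 1 & q_idx + rel[length(rel)] <= n
      bi <- bi[ok]; q_idx <- q_idx[ok]
      if (length(bi) < 3) next
      stack <- array(NA_real_, c(length(bi), length(rel), 12))
      for (j in seq_along(bi))
        stack[j, , ] <- recording$signal[q_idx[j] + rel, , drop = FALSE]
      medw <- apply(stack, c(2, 3), stats::median)
      colnames(medw) <- recording$leads
      hr <- 60000 / stats::median(beats$rr_ms[bi], na.rm = TRUE)
      qoff <- stats::median(beats$qrs_ms[bi], na.rm = TRUE)
      toff <- stats::median(beats$qt_ms[bi], na.rm = TRUE)
      if (!is.finite(hr) || !is.finite(qoff) || !is.finite(toff)) next
      mb_list[[s]] <- median_beat(medw, hr, qoff, toff, length(bi),
                                  segment_start = ws[s])
      seg_df$hr_bpm[s] <- hr; seg_df$n_beats[s] <- length(bi)
      seg_df$qrs_off_ms[s] <- qoff; seg_df$t_off_ms[s] <- toff
      seg_df$has_beat[s] <- TRUE
    }
  }
  structure(list(segments = seg_df, beats = mb_list, window = window),
            class = "median_beats")
}

#' Build the patient's heart-rate-matched baseline library
#'
#' Segments are binned by median heart rate into 5-bpm bins spanning
#' 40-140 bpm; each bin with at least `min_segments` contributing segments
#' gets a baseline beat equal to the sample-wise median of its segment
#' median beats, drawn from the patient's full recording.
#'
#' @param mbs a `"median_beats"` object.
#' @param min_segments minimum source segments per populated bin.
#' @return list of class `"baseline_library"`: `bins` (data.frame lo, hi,
#'   center, n_segments) and `beats` (list of [median_beat()] per populated
#'   bin).
#' @export
build_baseline_library <- function(mbs, min_segments = 10) {
  seg <- mbs$segments
  idx <- which(seg$has_beat)
  br <- HR_BIN_BREAKS
  nb <- length(br) - 1
  bins <- data.frame(lo = br[-length(br)], hi = br[-1],
                     center = (br[-length(br)] + br[-1]) / 2,
                     n_segments = 0L)
  beats <- vector("list", nb)
  if (length(idx)) {
    bin_of <- findInterval(seg$hr_bpm[idx], br)
    for (k in seq_len(nb)) {
      members <- idx[bin_of == k]
      bins$n_segments[k] <- length(members)
      if (length(members) < min_segments) next
      stack <- array(NA_real_,
                     c(length(members), length(MB_T_MS), 12))
      for (j in seq_along(members)) {
        mb <- mbs$beats[[members[j]]]
        # isoelectric-align each contributing beat so slow baseline offsets
        # do not leak into the pooled median
        stack[j, , ] <- sweep(mb$wave, 2, iso_level(mb), "-")
      }
      medw <- apply(stack, c(2, 3), stats::median)
      colnames(medw) <- colnames(mbs$beats[[members[1]]]$wave)
      beats[[k]] <- median_beat(
        medw, bins$center[k],
        stats::median(seg$qrs_off_ms[members]),
        stats::median(seg$t_off_ms[members]),
        length(members))
    }
  }
  if (!any(bins$n_segments >= min_segments))
    stop("insufficient baseline: no heart-rate bin reaches ",
         min_segments, " segments")
  structure(list(bins = bins, beats = beats, min_segments = min_segments),
            class = "baseline_library")
}

#' Match a heart rate to a populated baseline bin
#'
#' The segment's own bin if populated, else the nearest populated bin whose
#' center lies within `max_dist` bpm; `NA` otherwise (a segment is never
#' compared against a baseline more than 10 bpm away).
#'
#' @param lib a `"baseline_library"`.
#' @param hr_bpm segment heart rate.
#' @param max_dist maximum allowed |segment HR - bin center| (bpm).
#' @return bin index or `NA`.
#' @export
match_baseline_bin <- function(lib, hr_bpm, max_dist = 10) {
  pop <- which(!vapply(lib$beats, is.null, logical(1)))
  if (!length(pop) || !is.finite(hr_bpm)) return(NA_integer_)
  own <- findInterval(hr_bpm, HR_BIN_BREAKS)
  if (own >= 1 && own <= length(lib$beats) && own %in% pop) return(own)
  d <- abs(lib$bins$center[pop] - hr_bpm)
  if (min(d) > max_dist) return(NA_integer_)
  pop[which.min(d)]
}

# mean amplitude over a ms-window of a median beat, per lead
window_mean <- function(mb, lo_ms, hi_ms) {
  i <- mb$t_ms >= lo_ms & mb$t_ms <= hi_ms
  if (!any(i)) return(rep(NA_real_, ncol(mb$wave)))
  colMeans(mb$wave[i, , drop = FALSE])
}

iso_level <- function(mb) window_mean(mb, ISO_WIN[1], ISO_WIN[2])

#' ST deviation of a segment median beat against its baseline
#'
#' Mean amplitude over the ST window (J+40 to J+80 ms, J point = QRS
#' offset) of the segment beat minus the same quantity of the matched
#' baseline beat, after aligning both to their PQ-segment isoelectric
#' level.
#'
#' @param mb segment [median_beat()].
#' @param ref a baseline [median_beat()] or a `"baseline_library"` (the
#'   matched bin is then chosen by [match_baseline_bin()]).
#' @return named per-lead deviations (mV), all `NA` when no bin within
#'   10 bpm exists.
#' @export
st_deviation <- function(mb, ref) {
  ref <- resolve_baseline(ref, mb$hr_bpm)
  if (is.null(ref)) return(rep(NA_real_, ncol(mb$wave)))
  st_of <- function(b)
    window_mean(b, b$qrs_off_ms + ST_WIN[1], b$qrs_off_ms + ST_WIN[2]) -
      iso_level(b)
  st_of(mb) - st_of(ref)
}

#' T-wave amplitude deviations against the baseline
#'
#' Minimum and maximum amplitude over the T window (QRS offset + 80 ms to
#' T offset) of the segment beat minus those of the baseline beat,
#' isoelectric-aligned.
#'
#' @inheritParams st_deviation
#' @return list with per-lead vectors `tmin` and `tmax` (mV).
#' @export
t_wave_deviation <- function(mb, ref) {
  ref <- resolve_baseline(ref, mb$hr_bpm)
  nl <- ncol(mb$wave)
  if (is.null(ref)) return(list(tmin = rep(NA_real_, nl),
                                tmax = rep(NA_real_, nl)))
  rng <- function(b, f) {
    i <- b$t_ms >= b$qrs_off_ms + T_START_AFTER_J & b$t_ms <= b$t_off_ms
    if (!any(i)) return(rep(NA_real_, ncol(b$wave)))
    apply(b$wave[i, , drop = FALSE], 2, f) - iso_level(b)
  }
  list(tmin = rng(mb, min) - rng(ref, min),
       tmax = rng(mb, max) - rng(ref, max))
}

resolve_baseline <- function(ref, hr_bpm) {
  if (inherits(ref, "median_beat")) return(ref)
  if (inherits(ref, "baseline_library")) {
    k <- match_baseline_bin(ref, hr_bpm)
    if (is.na(k)) return(NULL)
    return(ref$beats[[k]])
  }
  stop("'ref' must be a median_beat or baseline_library")
}

#' Full deviation series of a recording against its baseline library
#'
#' @param mbs a `"median_beats"` object.
#' @param lib a `"baseline_library"`.
#' @param usable logical per-segment usability.
#' @param start_time POSIXct recording start (carried through).
#' @return a [deviation_series()]; deviations are defined only for usable
#'   segments with an available matched baseline bin.
#' @export
measure_deviations <- function(mbs, lib, usable = NULL, start_time = NULL) {
  seg <- mbs$segments
  S <- nrow(seg)
  if (is.null(usable)) usable <- seg$has_beat
  st <- matrix(NA_real_, S, 12)
  tmin <- matrix(NA_real_, S, 12)
  tmax <- matrix(NA_real_, S, 12)
  bin <- rep(NA_integer_, S)
  for (s in seq_len(S)) {
    if (!usable[s] || !seg$has_beat[s]) next
    mb <- mbs$beats[[s]]
    k <- match_baseline_bin(lib, mb$hr_bpm)
    if (is.na(k)) next
    bin[s] <- k
    st[s, ] <- st_deviation(mb, lib$beats[[k]])
    td <- t_wave_deviation(mb, lib$beats[[k]])
    tmin[s, ] <- td$tmin
    tmax[s, ] <- td$tmax
  }
  deviation_series(seg$segment_start, st, tmin, tmax,
                   usable & seg$has_beat,
                   leads = colnames(mbs$beats[[which(seg$has_beat)[1]]]$wave),
                   start_time = start_time, baseline_bin = bin)
}
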