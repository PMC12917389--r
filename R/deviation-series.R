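#' Per-segment, per-lead ST/T deviation series
#'
#' The common currency between the median-beat layer and the ischemia layer:
#' for every 10-s segment on the recording grid and every lead, the
#' ST-segment deviation and the deviations in minimum and maximum T-wave
#' amplitude relative to the patient's heart-rate-matched baseline, plus a
#' per-segment usability flag.
#'
#' @param segment_start numeric vector, segment start times (s since
#'   recording start), a regular 10-s grid.
#' @param st,tmin,tmax numeric matrices (segments x leads, mV); may contain
#'   `NA` where no matched baseline exists.
#' @param usable logical vector per segment.
#' @param leads character lead names (columns of the matrices).
#' @param start_time POSIXct recording start.
#' @param baseline_bin optional integer vector of matched baseline bin ids.
#' @return An object of class `"deviation_series"`.
#' @export
deviation_series <- function(segment_start, st, tmin, tmax, usable,
                             leads = HOLTER_LEADS,
                             start_time = NULL, baseline_bin = NULL) {
  S <- length(segment_start)
  for (m in list(st, tmin, tmax)) {
    stopifnot(is.matrix(m), nrow(m) == S, ncol(m) == length(leads))
  }
  stopifnot(length(usable) == S)
  if (S > 1 && max(abs(diff(segment_start) - SEG_LEN)) > 1e-6)
    stop("segment grid must be a regular 10-s grid")
  colnames(st) <- colnames(tmin) <- colnames(tmax) <- leads
  structure(list(segment_start = segment_start, seg_len = SEG_LEN,
                 leads = leads, st = st, tmin = tmin, tmax = tmax,
                 usable = as.logical(usable), start_time = start_time,
                 baseline_bin = baseline_bin),
            class = "deviation_series")
}

#' @export
print.deviation_series <- function(x, ...) {
  cat(sprintf("<deviation_series> %d segments x %d leads, %.1f%% usable\n",
              length(x$segment_start), length(x$leads),
              100 * mean(x$usable)))
  invisible(x)
}

#' Flatten a deviation series to a tidy data frame
#'
#' @param x a `"deviation_series"`.
#' @param usable_only drop unusable segments.
#' @return data.frame with columns segment_start, lead, st_dev_mv,
#'   tmin_dev_mv, tmax_dev_mv, baseline_bin.
#' @export
as.data.frame.deviation_series <- function(x, ..., usable_only = FALSE) {
  keep <- if (usable_only) which(x$usable) else seq_along(x$segment_start)
  L <- length(x$leads)
  out <- data.frame(
    segment_start = rep(x$segment_start[keep], times = L),
    lead = rep(x$leads, each = length(keep)),
    st_dev_mv = as.vector(x$st[keep, , drop = FALSE]),
    tmin_dev_mv = as.vector(x$tmin[keep, , drop = FALSE]),
    tmax_dev_mv = as.vector(x$tmax[keep, , drop = FALSE]),
    stringsAsFactors = FALSE
  )
  out$baseline_bin <- if (!is.null(x$baseline_bin))
    rep(x$baseline_bin[keep], times = L) else NA_integer_
  out
}
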