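# 24-hour and 10-second assessments: noon-to-noon day selection, 3-h
# circadian bins with group comparison, adjusted logistic models, the
# standardized resting 10-s segment, and Bazett's QT correction.

#' Select a full noon-to-noon day window
#'
#' A day runs from 12 PM to the next 12 PM on the recording's local clock
#' and qualifies only when fully inside the recording span with a usable
#' fraction of at least `min_usable_frac`.
#'
#' @param start_time POSIXct recording start.
#' @param span_s recording span (s).
#' @param iv interval series (for the usability fraction); `NULL` skips the
#'   usability qualification.
#' @param which `"first_full"` or `"last_full"`.
#' @param min_usable_frac minimum usable fraction for a day to qualify.
#' @return list of class `"day_window"`: `which`, `start_s`, `end_s`.
#' @export
select_day_window <- function(start_time, span_s, iv = NULL,
                              which = c("first_full", "last_full"),
                              min_usable_frac = 0.5) {
  which <- match.arg(which)
  lt <- as.POSIXlt(start_time, tz = "UTC")
  sec_of_day <- lt$hour * 3600 + lt$min * 60 + lt$sec
  first_noon <- (12 * 3600 - sec_of_day) %% 86400
  starts <- if (first_noon <= span_s)
    seq(first_noon, span_s, by = 86400) else numeric(0)
  starts <- starts[starts + 86400 <= span_s + 1e-6]
  if (!length(starts)) stop("no complete noon-to-noon day in the recording")
  if (!is.null(iv)) {
    ok <- vapply(starts, function(s) {
      w <- iv$window_start >= s & iv$window_start < s + 86400
      sum(w) > 0 && mean(iv$usable[w]) >= min_usable_frac
    }, logical(1))
    starts <- starts[ok]
    if (!length(starts)) stop("no qualifying day (usable fraction below ",
                              min_usable_frac, ")")
  }
  s <- if (which == "first_full") starts[1] else starts[length(starts)]
  structure(list(which = which, start_s = s, end_s = s + 86400,
                 start_time = start_time),
            class = "day_window")
}

#' Circadian profile over 3-hour bins
#'
#' Medians of heart rate, PQ, QRS, QT and Bazett QTc over the usable 10-s
#' windows falling in each of the 8 three-hour clock bins (starting at
#' 12 AM) of one noon-to-noon day, plus the median 5-min SDNN per bin.
#' Bin medians are absent when the bin holds fewer than `min_windows`
#' usable windows.
#'
#' @param iv interval series data.frame.
#' @param sdnn SDNN series data.frame (may be `NULL`).
#' @param window a [select_day_window()] result.
#' @param start_time POSIXct recording start.
#' @param min_windows minimum usable windows per bin.
#' @return data.frame: bin (1-8), hour_lo, hour_hi, hr, pq, qrs, qt, qtc,
#'   sdnn, n_windows.
#' @export
circadian_profile <- function(iv, sdnn, window, start_time,
                              min_windows = 10) {
  inw <- iv$window_start >= window$start_s & iv$window_start < window$end_s
  d <- iv[inw & iv$usable & !is.na(iv$hr_bpm), , drop = FALSE]
  h <- clock_hour(d$window_start, start_time)
  bin <- floor(h / 3) + 1L
  qtc <- qtc_bazett(d$qt_ms, 60000 / d$hr_bpm)
  out <- data.frame(bin = 1:8, hour_lo = 3 * (0:7), hour_hi = 3 * (1:8),
                    hr = NA_real_, pq = NA_real_, qrs = NA_real_,
                    qt = NA_real_, qtc = NA_real_, sdnn = NA_real_,
                    n_windows = 0L)
  for (b in 1:8) {
    i <- bin == b
    out$n_windows[b] <- sum(i)
    if (sum(i) < min_windows) next
    out$hr[b] <- stats::median(d$hr_bpm[i])
    out$pq[b] <- stats::median(d$pq_ms[i], na.rm = TRUE)
    out$qrs[b] <- stats::median(d$qrs_ms[i], na.rm = TRUE)
    out$qt[b] <- stats::median(d$qt_ms[i], na.rm = TRUE)
    out$qtc[b] <- stats::median(qtc[i], na.rm = TRUE)
  }
  if (!is.null(sdnn)) {
    ins <- sdnn$window_start >= window$start_s &
      sdnn$window_start < window$end_s & !is.na(sdnn$sdnn_ms)
    if (any(ins)) {
      hs <- clock_hour(sdnn$window_start[ins], start_time)
      bs <- floor(hs / 3) + 1L
      for (b in 1:8) {
        v <- sdnn$sdnn_ms[ins][bs == b]
        if (length(v) >= 2) out$sdnn[b] <- stats::median(v)
      }
    }
  }
  out
}

#' Group-level circadian summary across patients
#'
#' @param profiles list of per-patient [circadian_profile()] data.frames.
#' @param labels group label per patient.
#' @param measures profile columns to summarize.
#' @return data.frame: bin, measure, group, median, p2.5, p97.5, n.
#' @export
group_profile <- function(profiles, labels,
                          measures = c("hr", "pq", "qrs", "qt", "qtc",
                                       "sdnn")) {
  rows <- list()
  for (b in 1:8) for (m in measures) for (g in unique(labels)) {
    v <- vapply(profiles[labels == g], function(p) p[[m]][p$bin == b],
                numeric(1))
    v <- v[!is.na(v)]
    if (!length(v)) next
    q <- stats::quantile(v, c(0.025, 0.5, 0.975), names = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      bin = b, measure = m, group = g, median = q[2], p2.5 = q[1],
      p97.5 = q[3], n = length(v), stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Per-bin group comparison of circadian measures
#'
#' Test choice per bin and measure: Welch two-sample t-test when
#' Shapiro-Wilk does not reject normality (p > 0.05) in both groups, else
#' the Mann-Whitney U test; two-sided throughout.  Groups that are
#' constant or too small for Shapiro-Wilk are treated as non-normal.
#'
#' @param profiles list of per-patient profile data.frames.
#' @param labels group label per patient (exactly two groups).
#' @param measures profile columns to compare.
#' @param shapiro_alpha normality gate level.
#' @return data.frame: bin, measure, n1, n2, test, statistic, p.
#' @export
compare_bins <- function(profiles, labels,
                         measures = c("hr", "pq", "qrs", "qt", "qtc",
                                      "sdnn"),
                         shapiro_alpha = 0.05) {
  gs <- unique(labels)
  stopifnot(length(gs) == 2)
  rows <- list()
  for (b in 1:8) for (m in measures) {
    v1 <- vapply(profiles[labels == gs[1]], function(p) p[[m]][p$bin == b],
                 numeric(1))
    v2 <- vapply(profiles[labels == gs[2]], function(p) p[[m]][p$bin == b],
                 numeric(1))
    v1 <- v1[!is.na(v1)]; v2 <- v2[!is.na(v2)]
    if (length(v1) < 2 || length(v2) < 2) next
    res <- compare_two_samples(v1, v2, shapiro_alpha)
    rows[[length(rows) + 1L]] <- data.frame(
      bin = b, measure = m, n1 = length(v1), n2 = length(v2),
      test = res$test, statistic = res$statistic, p = res$p,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Two-sample comparison with the declared normality gate
#' @param v1,v2 numeric samples.
#' @param shapiro_alpha normality gate level.
#' @return list(test, statistic, p).
#' @export
compare_two_samples <- function(v1, v2, shapiro_alpha = 0.05) {
  normal_ok <- function(v) {
    if (length(v) < 3 || length(unique(v)) < 3 || length(v) > 5000)
      return(FALSE)
    stats::shapiro.test(v)$p.value > shapiro_alpha
  }
  if (normal_ok(v1) && normal_ok(v2)) {
    tt <- stats::t.test(v1, v2, var.equal = FALSE)
    list(test = "welch_t", statistic = unname(tt$statistic), p = tt$p.value)
  } else {
    wt <- suppressWarnings(stats::wilcox.test(v1, v2, exact = FALSE,
                                              correct = TRUE))
    p <- wt$p.value
    if (is.nan(p)) p <- 1   # both samples constant at the same value
    list(test = "mann_whitney", statistic = unname(wt$statistic), p = p)
  }
}

#' Unadjusted and adjusted logistic regression for a Holter feature
#'
#' Maximum-likelihood fits of disease status on the feature, without and
#' with the covariates; odds ratios per unit feature with Wald intervals.
#' Complete separation or non-convergence is flagged and no estimate is
#' reported for the affected model.
#'
#' @param data data.frame containing `label` (logical or 0/1) and the named
#'   columns.
#' @param feature feature column name.
#' @param covariates covariate column names for the adjusted model.
#' @return list of class `"logistic_result"` with `unadjusted` and
#'   `adjusted`, each either `list(or, ci_lo, ci_hi, p)` or `NULL` when
#'   flagged, plus `separation` flags.
#' @export
adjusted_logistic <- function(data, feature,
                              covariates = c("age", "sex", "beta_blocker",
                                             "rate_limiting_ccb")) {
  fit_one <- function(fml) {
    sep <- FALSE
    fit <- withCallingHandlers(
      stats::glm(fml, family = stats::binomial(), data = data),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                  conditionMessage(w))) sep <<- TRUE
        invokeRestart("muffleWarning")
      })
    co <- summary(fit)$coefficients
    if (sep || !fit$converged || abs(co[feature, "Estimate"]) > 15)
      return(list(est = NULL, separation = TRUE))
    b <- co[feature, "Estimate"]; se <- co[feature, "Std. Error"]
    z <- stats::qnorm(0.975)
    list(est = list(or = exp(b), ci_lo = exp(b - z * se),
                    ci_hi = exp(b + z * se),
                    p = co[feature, "Pr(>|z|)"], log_or = b),
         separation = FALSE)
  }
  f_un <- stats::reformulate(feature, response = "label")
  f_ad <- stats::reformulate(c(feature, covariates), response = "label")
  un <- fit_one(f_un); ad <- fit_one(f_ad)
  structure(list(unadjusted = un$est, adjusted = ad$est,
                 separation = c(unadjusted = un$separation,
                                adjusted = ad$separation)),
            class = "logistic_result")
}

#' Select the standardized resting 10-s segment
#'
#' Among usable, symptom-free (no merged symptom within +/-15 min) 10-s
#' windows between 06:30 and 08:30 local time on the preferred day, the
#' window whose heart rate is closest to 75 bpm; ties break to the
#' earliest window.  If the preferred day has no candidate, the next day
#' in `days_pref` is used.
#'
#' @param iv interval series data.frame.
#' @param symptoms merged symptoms (from [merge_symptoms()]), may be empty.
#' @param start_time POSIXct recording start.
#' @param days_pref Date vector in preference order; default the last
#'   calendar date with any 06:30-08:30 coverage, then the previous one.
#' @param target_hr target heart rate (bpm).
#' @param symptom_margin_s symptom-free margin (s).
#' @return list of class `"resting_10s"`: `segment_start`, `date`,
#'   `hr_bpm`, `pq_ms`, `qrs_ms`, `qt_ms`, `qtc_ms`; or `NULL` (with a
#'   message) when no candidate exists on any eligible day.
#' @export
select_resting_10s <- function(iv, symptoms, start_time, days_pref = NULL,
                               target_hr = 75, symptom_margin_s = 900) {
  h <- clock_hour(iv$window_start, start_time)
  band <- h >= 6.5 & h < 8.5
  cand <- iv$usable & band & !is.na(iv$hr_bpm)
  if (!is.null(symptoms) && nrow(symptoms)) {
    s_t <- as.numeric(symptoms$timestamp) - as.numeric(start_time)
    near <- vapply(iv$window_start, function(w)
      any(abs(s_t - (w + SEG_LEN / 2)) <= symptom_margin_s +
            SEG_LEN / 2), logical(1))
    cand <- cand & !near
  }
  dates <- as.Date(start_time + iv$window_start, tz = "UTC")
  if (is.null(days_pref)) {
    dd <- sort(unique(dates[band]), decreasing = TRUE)
    days_pref <- dd[seq_len(min(2, length(dd)))]
  }
  for (d in as.list(days_pref)) {
    i <- which(cand & dates == d)
    if (!length(i)) next
    best <- i[order(abs(iv$hr_bpm[i] - target_hr), iv$window_start[i])][1]
    hr <- iv$hr_bpm[best]
    return(structure(list(
      segment_start = iv$window_start[best], date = d, hr_bpm = hr,
      pq_ms = iv$pq_ms[best], qrs_ms = iv$qrs_ms[best],
      qt_ms = iv$qt_ms[best],
      qtc_ms = qtc_bazett(iv$qt_ms[best], 60000 / hr)),
      class = "resting_10s"))
  }
  message("no resting 10-s candidate on any eligible day")
  NULL
}

#' Bazett heart-rate-corrected QT
#'
#' `QTc = QT / sqrt(RR)` with RR in seconds; equals QT at RR = 1000 ms.
#'
#' @param qt_ms QT interval (ms).
#' @param rr_ms RR interval (ms), > 0.
#' @return QTc (ms).
#' @export
qtc_bazett <- function(qt_ms, rr_ms) {
  if (any(rr_ms <= 0, na.rm = TRUE)) stop("RR must be positive")
  qt_ms / sqrt(rr_ms / 1000)
}

#' Prolonged-QTc flag
#'
#' Conventional clinical cutoffs: 460 ms for females, 450 ms for males.
#'
#' @param qtc_ms QTc (ms).
#' @param sex `"F"` or `"M"`.
#' @param cutoff_f,cutoff_m cutoffs (ms).
#' @return logical.
#' @export
qtc_prolonged <- function(qtc_ms, sex, cutoff_f = 460, cutoff_m = 450) {
  ifelse(sex == "F", qtc_ms >= cutoff_f, qtc_ms >= cutoff_m)
}
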