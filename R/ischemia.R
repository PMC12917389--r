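# Ischemia layer: deviation series -> events under the contiguous-lead /
# minimum-duration rule, normalized daily burden, cutoff sweep, and symptom
# concurrency.

#' Exceedance magnitude of a deviation series for one parameter
#'
#' `st_depression` counts deviations at or below `-cutoff` (magnitude is
#' `-st`), `st_elevation` at or above `+cutoff` (magnitude `+st`), and
#' `st_deviation`, `tmin_deviation`, `tmax_deviation` use the absolute
#' deviation.
#'
#' @param dev a [deviation_series()].
#' @param parameter one of st_deviation, st_elevation, st_depression,
#'   tmin_deviation, tmax_deviation.
#' @return segments x leads magnitude matrix (mV); `NA` where undefined.
#' @keywords internal
exceedance_magnitude <- function(dev, parameter) {
  switch(parameter,
         st_deviation = abs(dev$st),
         st_elevation = dev$st,
         st_depression = -dev$st,
         tmin_deviation = abs(dev$tmin),
         tmax_deviation = abs(dev$tmax),
         stop("unknown parameter: ", parameter))
}

#' Detect ischemia events
#'
#' A 10-s segment qualifies when at least two contiguous leads (see
#' [contiguous_pairs()]) exceed the cutoff; an event is a maximal run of at
#' least `min_run` consecutive qualifying usable segments (>= 30 s).  Under
#' the default `"pair_stable"` rule the exceedance must hold in the same
#' contiguous pair throughout a run; `"any_pair"` only requires some pair
#' per segment.  Unusable segments break a run.  Runs from different pairs
#' whose covered segments touch or overlap merge into one event whose lead
#' set is the union of the contributing pairs.
#'
#' @param dev a [deviation_series()].
#' @param parameter ischemia parameter (see [exceedance_magnitude()]).
#' @param cutoff threshold in mV (>= 0).
#' @param rule contiguity reading, `"pair_stable"` (default) or
#'   `"any_pair"`.
#' @param min_run minimum number of consecutive qualifying segments.
#' @return data.frame of events: `start`, `end` (s), `duration_s`, `leads`
#'   (comma-separated), `peak_mv` (peak exceedance magnitude), `parameter`,
#'   `cutoff`.
#' @export
detect_events <- function(dev, parameter, cutoff,
                          rule = c("pair_stable", "any_pair"),
                          min_run = 3L) {
  rule <- match.arg(rule)
  stopifnot(cutoff >= 0)
  parameter <- match.arg(parameter, ISCHEMIA_PARAMETERS)
  mag <- exceedance_magnitude(dev, parameter)
  S <- nrow(mag)
  pairs <- contiguous_pairs()
  np <- nrow(pairs)
  qual <- matrix(FALSE, S, np)
  for (p in seq_len(np)) {
    a <- match(pairs[p, 1], dev$leads); b <- match(pairs[p, 2], dev$leads)
    q <- pmin(mag[, a], mag[, b]) >= cutoff
    q[is.na(q)] <- FALSE
    qual[, p] <- q & dev$usable
  }
  covered <- logical(S)
  pair_runs <- list()
  if (rule == "pair_stable") {
    for (p in seq_len(np)) {
      r <- rle(qual[, p])
      e <- cumsum(r$lengths); s <- e - r$lengths + 1L
      ok <- which(r$values & r$lengths >= min_run)
      for (k in ok) {
        covered[s[k]:e[k]] <- TRUE
        pair_runs[[length(pair_runs) + 1L]] <-
          list(pair = p, s = s[k], e = e[k])
      }
    }
  } else {
    any_q <- rowSums(qual) > 0
    r <- rle(any_q)
    e <- cumsum(r$lengths); s <- e - r$lengths + 1L
    ok <- which(r$values & r$lengths >= min_run)
    for (k in ok) {
      covered[s[k]:e[k]] <- TRUE
      for (p in which(colSums(qual[s[k]:e[k], , drop = FALSE]) > 0))
        pair_runs[[length(pair_runs) + 1L]] <-
          list(pair = p, s = s[k], e = e[k])
    }
  }
  empty <- data.frame(start = numeric(0), end = numeric(0),
                      duration_s = numeric(0), leads = character(0),
                      peak_mv = numeric(0), parameter = character(0),
                      cutoff = numeric(0), stringsAsFactors = FALSE)
  if (!any(covered)) return(empty)
  r <- rle(covered)
  e <- cumsum(r$lengths); s <- e - r$lengths + 1L
  ev_idx <- which(r$values)
  out <- lapply(ev_idx, function(k) {
    i <- s[k]; j <- e[k]
    touching <- vapply(pair_runs, function(pr) pr$s <= j && pr$e >= i,
                       logical(1))
    leads <- unique(as.vector(pairs[unique(vapply(
      pair_runs[touching], function(pr) pr$pair, integer(1))), ,
      drop = FALSE]))
    leads <- leads[order(match(leads, HOLTER_LEADS))]
    jcol <- match(leads, dev$leads)
    data.frame(start = dev$segment_start[i],
               end = dev$segment_start[j] + dev$seg_len,
               duration_s = (j - i + 1) * dev$seg_len,
               leads = paste(leads, collapse = ","),
               peak_mv = max(mag[i:j, jcol], na.rm = TRUE),
               parameter = parameter, cutoff = cutoff,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Normalized daily ischemia burden
#'
#' Total event duration rescaled to seconds per 24 h of usable recording,
#' with the >= 1 min/day positivity flag.
#'
#' @param events event data.frame from [detect_events()].
#' @param usable_duration usable recording duration (s), > 0.
#' @return list of class `"burden_summary"`: `total_s`, `usable_s`,
#'   `normalized_s_day`, `flag_1min`.
#' @export
burden <- function(events, usable_duration) {
  if (usable_duration <= 0) stop("usable duration must be positive")
  total <- sum(events$duration_s)
  norm <- total * 86400 / usable_duration
  structure(list(total_s = total, usable_s = usable_duration,
                 normalized_s_day = norm, flag_1min = norm >= 60),
            class = "burden_summary")
}

# per-patient burden flags over a cutoff grid
sweep_flags <- function(dev, usable_duration, parameter, cutoffs,
                        rule = "pair_stable", min_run = 3L) {
  vapply(cutoffs, function(cf) {
    ev <- detect_events(dev, parameter, cf, rule = rule, min_run = min_run)
    burden(ev, usable_duration)$flag_1min
  }, logical(1))
}

#' Cutoff sweep of burden positivity with group comparison
#'
#' For every cutoff on the grid, computes each patient's >= 1 min/day
#' burden flag, the per-group positive proportions with Wilson 95%
#' intervals, and a two-sided Fisher exact p per cutoff.
#'
#' @param devs named list of [deviation_series()], one per patient.
#' @param usable_durations numeric vector of usable durations (s), aligned
#'   with `devs`.
#' @param labels group labels (`"CAS"` / `"noCAS"`), aligned with `devs`.
#' @param parameter ischemia parameter.
#' @param cutoffs cutoff grid in mV (default 0 to 0.5 by 0.005).
#' @param rule contiguity reading passed to [detect_events()].
#' @return list of class `"sweep_result"`: `flags` (patients x cutoffs
#'   logical matrix), `cutoffs`, `labels`, and `table` (tidy data.frame:
#'   cutoff, group, n_pos, n, prop, wilson_lo, wilson_hi, fisher_p).
#' @export
threshold_sweep <- function(devs, usable_durations, labels, parameter,
                            cutoffs = seq(0, 0.5, by = 0.005),
                            rule = "pair_stable") {
  stopifnot(length(devs) == length(labels),
            length(devs) == length(usable_durations),
            length(unique(labels)) >= 1)
  n <- length(devs)
  flags <- matrix(NA, n, length(cutoffs),
                  dimnames = list(names(devs), NULL))
  for (i in seq_len(n))
    flags[i, ] <- sweep_flags(devs[[i]], usable_durations[i], parameter,
                              cutoffs, rule = rule)
  groups <- unique(labels)
  rows <- list()
  for (ci in seq_along(cutoffs)) {
    tab2 <- vapply(groups, function(g) {
      f <- flags[labels == g, ci]
      c(sum(f), length(f))
    }, numeric(2))
    p_f <- if (length(groups) == 2)
      fisher_exact(two_by_two_counts(tab2[1, 1], tab2[1, 2],
                                     tab2[2, 1], tab2[2, 2]))
    else NA_real_
    for (g in groups) {
      k <- sum(flags[labels == g, ci]); m <- sum(labels == g)
      w <- wilson_ci(k, m)
      rows[[length(rows) + 1L]] <- data.frame(
        cutoff = cutoffs[ci], group = g, n_pos = k, n = m, prop = k / m,
        wilson_lo = w[1], wilson_hi = w[2], fisher_p = p_f,
        stringsAsFactors = FALSE)
    }
  }
  structure(list(flags = flags, cutoffs = cutoffs, labels = labels,
                 parameter = parameter, rule = rule,
                 table = do.call(rbind, rows)),
            class = "sweep_result")
}

# helper building a TwoByTwo from a flag cross-tab (diseased pos, non-diseased
# pos, group sizes)
two_by_two_counts <- function(pos_d, neg_d, n_d, n_nd) {
  two_by_two(flags = c(rep(TRUE, pos_d), rep(FALSE, n_d - pos_d),
                       rep(TRUE, neg_d), rep(FALSE, n_nd - neg_d)),
             labels = c(rep(TRUE, n_d), rep(FALSE, n_nd)))
}

#' Merge diary and button symptom streams into unique symptoms
#'
#' A button press and a diary entry of the same type within `tol_s` of each
#' other are one symptom; the diary timestamp is kept.
#'
#' @param log symptom log data.frame (columns patient_id, source,
#'   timestamp, type, ...).
#' @param tol_s dedup window (s), default 10 min.
#' @return data.frame of merged symptoms: patient_id, timestamp, type,
#'   source (`diary`, `button`, or `both`).
#' @export
merge_symptoms <- function(log, tol_s = 600) {
  if (nrow(log) == 0)
    return(data.frame(patient_id = character(0),
                      timestamp = as.POSIXct(character(0), tz = "UTC"),
                      type = character(0), source = character(0),
                      stringsAsFactors = FALSE))
  di <- log[log$source == "diary", , drop = FALSE]
  bu <- log[log$source == "button", , drop = FALSE]
  matched <- logical(nrow(bu))
  src_d <- rep("diary", nrow(di))
  if (nrow(bu) && nrow(di)) {
    for (i in seq_len(nrow(bu))) {
      same <- which(di$type == bu$type[i] &
                      abs(as.numeric(di$timestamp) -
                            as.numeric(bu$timestamp[i])) <= tol_s)
      if (length(same)) {
        matched[i] <- TRUE
        src_d[same[which.min(abs(as.numeric(di$timestamp[same]) -
                                   as.numeric(bu$timestamp[i])))]] <- "both"
      }
    }
  }
  out <- rbind(
    data.frame(patient_id = di$patient_id, timestamp = di$timestamp,
               type = di$type, source = src_d, stringsAsFactors = FALSE),
    data.frame(patient_id = bu$patient_id[!matched],
               timestamp = bu$timestamp[!matched],
               type = bu$type[!matched],
               source = rep("button", sum(!matched)),
               stringsAsFactors = FALSE))
  out[order(out$timestamp), , drop = FALSE]
}

#' Concurrency of acute symptoms with ischemia events
#'
#' A symptom is concurrent iff any event overlaps the closed window
#' [onset - 30 min, onset + 30 min].  Patients with zero acute symptoms get
#' an absent percentage and `flag_any_concurrent = FALSE` (they are kept in
#' downstream 2x2 tables with a negative flag).
#'
#' @param events event data.frame from [detect_events()].
#' @param symptoms merged symptoms from [merge_symptoms()].
#' @param start_time POSIXct recording start (converts timestamps to
#'   seconds on the event clock).
#' @param window half-width of the concurrency window (s).
#' @param acute_types symptom types counted as acute.
#' @return list of class `"concurrency_result"`: `n_acute`,
#'   `n_concurrent`, `pct_concurrent` (`NA` when no acute symptoms),
#'   `flag_any_concurrent`.
#' @export
symptom_concurrency <- function(events, symptoms, start_time,
                                window = 1800,
                                acute_types = c("chest_pain", "dyspnea")) {
  ac <- symptoms[symptoms$type %in% acute_types, , drop = FALSE]
  n <- nrow(ac)
  if (n == 0)
    return(structure(list(n_acute = 0L, n_concurrent = 0L,
                          pct_concurrent = NA_real_,
                          flag_any_concurrent = FALSE),
                     class = "concurrency_result"))
  t_s <- as.numeric(ac$timestamp) - as.numeric(start_time)
  conc <- vapply(t_s, function(t) {
    nrow(events) > 0 &&
      any(events$start <= t + window & events$end >= t - window)
  }, logical(1))
  structure(list(n_acute = n, n_concurrent = sum(conc),
                 pct_concurrent = 100 * sum(conc) / n,
                 flag_any_concurrent = any(conc)),
            class = "concurrency_result")
}
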