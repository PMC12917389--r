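# Event detection under the contiguity/duration rule, burden, sweep,
# symptom concurrency.

zeros_dev <- function(S = 60) {
  z <- matrix(0, S, 12, dimnames = list(NULL, HOLTER_LEADS))
  deviation_series((0:(S - 1)) * 10, z, z, z, rep(TRUE, S))
}

test_that("the contiguity and 30-s rules shape events exactly", {
  expect_equal(nrow(detect_events(zeros_dev(), "st_depression", 0.035)), 0)

  d <- zeros_dev()
  d$st[10:12, c("V4", "V5")] <- -0.05
  ev <- detect_events(d, "st_depression", 0.035)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$duration_s, 30)
  expect_equal(ev$leads, "V4,V5")
  expect_equal(ev$start, 90)
  expect_equal(ev$end, 120)

  # a single exceeding lead never yields an event
  d2 <- zeros_dev()
  d2$st[1:60, "V2"] <- -0.2
  expect_equal(nrow(detect_events(d2, "st_depression", 0.035)), 0)

  # two qualifying segments are below the 30-s minimum
  d3 <- zeros_dev()
  d3$st[10:11, c("V4", "V5")] <- -0.05
  expect_equal(nrow(detect_events(d3, "st_depression", 0.035)), 0)

  # an unusable segment breaks the run
  d4 <- zeros_dev()
  d4$st[10:14, c("V4", "V5")] <- -0.05
  d4$usable[12] <- FALSE
  expect_equal(nrow(detect_events(d4, "st_depression", 0.035)), 0)

  expect_error(detect_events(d, "not_a_parameter", 0.035), "unknown|arg")
})

test_that("parameter semantics: depression, elevation, absolute deviations", {
  d <- zeros_dev()
  d$st[5:8, c("II", "III")] <- 0.06     # elevation
  d$st[20:23, c("V5", "V6")] <- -0.06   # depression
  expect_equal(detect_events(d, "st_elevation", 0.05)$leads, "II,III")
  expect_equal(detect_events(d, "st_depression", 0.05)$leads, "V5,V6")
  ev <- detect_events(d, "st_deviation", 0.05)
  expect_equal(nrow(ev), 2)
  d$tmin[30:33, c("V1", "V2")] <- -0.08
  expect_equal(detect_events(d, "tmin_deviation", 0.05)$leads, "V1,V2")
})

test_that("events match the brute-force per-segment scanner on random grids", {
  for (seed in 1:120) {
    d <- random_dev_grid(S = 20, seed = seed)
    for (rule in c("pair_stable", "any_pair")) {
      got <- detect_events(d, "st_depression", 0.035, rule = rule)
      want <- brute_force_events(d, "st_depression", 0.035, rule = rule)
      expect_equal(got[, c("start", "end", "duration_s", "leads",
                           "peak_mv")],
                   want, ignore_attr = TRUE,
                   label = sprintf("seed %d rule %s", seed, rule))
    }
  }
})

test_that("burden normalizes to seconds per usable 24 h", {
  ev <- data.frame(duration_s = c(30, 30))
  b <- burden(ev, 86400)
  expect_equal(b$normalized_s_day, 60)
  expect_true(b$flag_1min)

  b2 <- burden(data.frame(duration_s = 30), 43200)
  expect_equal(b2$normalized_s_day, 60)
  expect_true(b2$flag_1min)

  b3 <- burden(data.frame(duration_s = numeric(0)), 86400)
  expect_equal(b3$normalized_s_day, 0)
  expect_false(b3$flag_1min)

  expect_error(burden(ev, 0), "positive")
})

test_that("burden is additive over disjoint recording halves", {
  d <- random_dev_grid(S = 40, seed = 7)
  d$usable[] <- TRUE
  full <- detect_events(d, "st_depression", 0.03)
  half1 <- deviation_series(d$segment_start[1:20], d$st[1:20, ],
                            d$tmin[1:20, ], d$tmax[1:20, ], d$usable[1:20])
  half2 <- deviation_series(d$segment_start[21:40] - 200, d$st[21:40, ],
                            d$tmin[21:40, ], d$tmax[21:40, ],
                            d$usable[21:40])
  e1 <- detect_events(half1, "st_depression", 0.03)
  e2 <- detect_events(half2, "st_depression", 0.03)
  # events crossing the split boundary may be lost or shortened there, so
  # compare with events that lie strictly inside one half
  inner <- full[full$end <= 200 | full$start >= 200, ]
  expect_gte(sum(e1$duration_s) + sum(e2$duration_s),
             sum(inner$duration_s))
})

test_that("per-patient flags are monotone non-increasing in the cutoff", {
  cutoffs <- seq(0, 0.1, by = 0.005)
  for (seed in 1:15) {
    d <- random_dev_grid(S = 40, seed = 400 + seed)
    fl <- holterst:::sweep_flags(d, 400 * 10, "st_depression", cutoffs)
    expect_true(all(diff(fl) <= 0))
  }
})

test_that("a nonzero sustained deviation flags at cutoff zero", {
  d <- zeros_dev()
  d$st[1:6, c("I", "aVL")] <- -0.01
  sw <- threshold_sweep(list(p1 = d), 600, "CAS", "st_depression",
                        cutoffs = c(0, 0.035))
  expect_true(sw$flags[1, 1])
  expect_false(sw$flags[1, 2])
})

test_that("sweep recovers injected group separation on a small cohort", {
  co <- generate_cohort(12, 12, seed = 301, days = 1, symptom_logs = FALSE)
  bf <- cohort_burden(co, "st_depression", 0.035)
  truth <- vapply(co$patients, function(p) p$truth$burden_state == 1,
                  logical(1))
  expect_equal(bf$flag, truth)
})

test_that("injected supra-cutoff episodes are detected with high sensitivity", {
  hits <- 0; total <- 0
  for (i in 1:20) {
    sp <- cohort_defaults("CAS", seed = 600 + i, p_burden = 1,
                          artifact_frac = 0.02)   # low-noise condition
    x <- simulate_segments(sp, days = 1)
    ev <- detect_events(x$deviations, "st_depression", 0.035)
    eps <- x$truth$episodes
    eps <- eps[eps$amplitude_mv <= -0.045 & eps$duration_s >= 40, ]
    for (k in seq_len(nrow(eps))) {
      total <- total + 1
      if (nrow(ev) && any(ev$start < eps$end[k] & ev$end > eps$start[k]))
        hits <- hits + 1
    }
  }
  expect_gte(hits / total, 0.95)
})

test_that("diary/button dedup keeps the diary timestamp of paired reports", {
  t0 <- as.POSIXct("2024-03-11 10:00:00", tz = "UTC")
  log <- data.frame(
    patient_id = "P1",
    source = c("diary", "button", "button", "diary"),
    timestamp = t0 + c(100, 400, 5000, 9000),
    type = c("chest_pain", "chest_pain", "dyspnea", "dyspnea"),
    duration_min = c(10, NA, NA, 5), stringsAsFactors = FALSE)
  m <- merge_symptoms(log)
  expect_equal(nrow(m), 3)   # first two merge (same type, 300 s apart)
  expect_equal(m$source[1], "both")
  expect_equal(as.numeric(m$timestamp[1] - t0, units = "secs"), 100)
  # same pair but different types stays separate
  log2 <- log; log2$type[2] <- "fatigue"
  expect_equal(nrow(merge_symptoms(log2)), 4)
})

test_that("concurrency window is closed at +/-30 min", {
  t0 <- as.POSIXct("2024-03-11 10:00:00", tz = "UTC")
  sym <- data.frame(patient_id = "P1", timestamp = t0 + 7200,
                    type = "chest_pain", source = "diary",
                    stringsAsFactors = FALSE)
  ev_in <- data.frame(start = 7200 + 29 * 60, end = 7200 + 31 * 60)
  cc <- symptom_concurrency(ev_in, sym, t0)
  expect_equal(cc$n_concurrent, 1)
  ev_edge <- data.frame(start = 7200 - 3600, end = 7200 - 1800)
  expect_equal(symptom_concurrency(ev_edge, sym, t0)$n_concurrent, 1)
  ev_out <- data.frame(start = 7200 - 3660, end = 7200 - 31 * 60)
  expect_equal(symptom_concurrency(ev_out, sym, t0)$n_concurrent, 0)
})

test_that("concurrency percentages and the no-symptom convention", {
  t0 <- as.POSIXct("2024-03-11 10:00:00", tz = "UTC")
  sym <- data.frame(
    patient_id = "P1", timestamp = t0 + c(1, 5, 9, 13) * 3600,
    type = c("chest_pain", "dyspnea", "chest_pain", "fatigue"),
    source = "diary", stringsAsFactors = FALSE)
  ev <- data.frame(start = 3600 + 600, end = 3600 + 900)
  cc <- symptom_concurrency(ev, sym, t0)
  expect_equal(cc$n_acute, 3)      # fatigue is not acute
  expect_equal(cc$n_concurrent, 1)
  expect_equal(cc$pct_concurrent, 100 / 3)

  none <- symptom_concurrency(ev, sym[sym$type == "fatigue", ], t0)
  expect_equal(none$n_acute, 0)
  expect_true(is.na(none$pct_concurrent))
  expect_false(none$flag_any_concurrent)
})

test_that("4 acute symptoms with 1 concurrent give 25%", {
  t0 <- as.POSIXct("2024-03-11 10:00:00", tz = "UTC")
  sym <- data.frame(patient_id = "P1",
                    timestamp = t0 + c(1, 5, 9, 13) * 3600,
                    type = "chest_pain", source = "diary",
                    stringsAsFactors = FALSE)
  ev <- data.frame(start = 3600, end = 3900)
  expect_equal(symptom_concurrency(ev, sym, t0)$pct_concurrent, 25)
})
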