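# Day-window selection, 3-h circadian bins, group comparison, logistic
# models, resting 10-s selection, Bazett QTc.

t_mon10 <- as.POSIXct("2024-03-11 10:00:00", tz = "UTC")

test_that("noon-to-noon day selection follows the calendar", {
  # Mon 10 AM to Thu 9 AM: first full day Mon->Tue, last Tue->Wed
  span <- 71 * 3600
  f <- select_day_window(t_mon10, span, NULL, "first_full")
  l <- select_day_window(t_mon10, span, NULL, "last_full")
  expect_equal(f$start_s, 2 * 3600)           # Mon 12 PM
  expect_equal(l$start_s, 2 * 3600 + 86400)   # Tue 12 PM
  expect_equal(f$end_s - f$start_s, 86400)

  # Mon 1 PM to Tue 11 AM: no complete noon-to-noon day
  t_mon13 <- as.POSIXct("2024-03-11 13:00:00", tz = "UTC")
  expect_error(select_day_window(t_mon13, 22 * 3600, NULL), "no complete")

  # exactly one full day: first == last
  f1 <- select_day_window(t_mon10, 26 * 3600 + 10, NULL, "first_full")
  l1 <- select_day_window(t_mon10, 26 * 3600 + 10, NULL, "last_full")
  expect_equal(f1$start_s, l1$start_s)
})

test_that("days below the usable-fraction floor are disqualified", {
  # start at midnight; noon-to-noon candidates begin at 43200 and 129600
  iv <- data.frame(window_start = (0:(8640 * 3 - 1)) * 10)
  iv$usable <- iv$window_start >= 129600   # first 1.5 days unusable
  w <- select_day_window(t_mon10 - 10 * 3600, 3 * 86400, iv, "first_full")
  expect_equal(w$start_s, 129600)
  iv$usable <- FALSE
  expect_error(select_day_window(t_mon10 - 10 * 3600, 3 * 86400, iv),
               "no qualifying day")
})

test_that("circadian bins are clock-aligned medians with a 10-window floor", {
  sp <- cohort_defaults("CAS", seed = 91, hr_amp = 0, hr_mesor = 70,
                        hr_window_sd = 0, artifact_frac = 0)
  x <- simulate_segments(sp, days = 2)
  w <- select_day_window(x$start_time, x$span_s, x$interval_series,
                         "last_full")
  pr <- circadian_profile(x$interval_series, x$sdnn_series, w,
                          x$start_time)
  expect_equal(pr$hr, rep(70, 8), tolerance = 1e-6)

  # nocturnal dip localizes in the 3-6 AM neighbourhood
  sp2 <- cohort_defaults("CAS", seed = 92)
  x2 <- simulate_segments(sp2, days = 2)
  w2 <- select_day_window(x2$start_time, x2$span_s, x2$interval_series,
                          "last_full")
  pr2 <- circadian_profile(x2$interval_series, x2$sdnn_series, w2,
                           x2$start_time)
  expect_lt(mean(pr2$hr[1:2]), min(pr2$hr[5:6]) - 5)
  expect_gt(mean(pr2$pq[1:2]), mean(pr2$pq[5:6]))   # nocturnal PQ rise

  # a bin with fewer than 10 usable windows reports nothing
  iv <- x$interval_series
  iv$usable[holterst:::clock_hour(iv$window_start, x$start_time) < 3] <- FALSE
  pr3 <- circadian_profile(iv, NULL, w, x$start_time)
  expect_true(is.na(pr3$hr[1]))
})

test_that("bin medians are invariant to within-bin reordering", {
  sp <- cohort_defaults("noCAS", seed = 93)
  x <- simulate_segments(sp, days = 2)
  w <- select_day_window(x$start_time, x$span_s, NULL, "last_full")
  iv <- x$interval_series
  set.seed(1); perm <- sample(nrow(iv))
  pr1 <- circadian_profile(iv, NULL, w, x$start_time)
  pr2 <- circadian_profile(iv[perm, ], NULL, w, x$start_time)
  expect_equal(pr1$hr, pr2$hr)
  expect_equal(pr1$qtc, pr2$qtc)
})

test_that("test choice follows the normality gate and handles degenerate ties", {
  r <- compare_two_samples(rnorm(20, 0, 1), rnorm(20, 0.2, 1))
  expect_true(r$test %in% c("welch_t", "mann_whitney"))
  # heavy-tailed data routes to Mann-Whitney
  set.seed(42)
  r2 <- compare_two_samples(rexp(30)^3, rexp(30)^3)
  expect_equal(r2$test, "mann_whitney")
  # both groups constant at the same value: p = 1 by convention
  r3 <- compare_two_samples(rep(5, 10), rep(5, 10))
  expect_equal(r3$p, 1)
  # a clear shift is detected
  set.seed(7)
  r4 <- compare_two_samples(rnorm(33, 60, 5), rnorm(9, 70, 4))
  expect_lt(r4$p, 0.01)
})

test_that("compare_bins emits one row per bin and measure with both groups present", {
  mk_prof <- function(seed, hr0) {
    set.seed(seed)
    data.frame(bin = 1:8, hr = hr0 + rnorm(8), pq = 160 + rnorm(8),
               qrs = 92, qt = 400, qtc = 440, sdnn = 30)
  }
  profiles <- c(lapply(1:6, function(i) mk_prof(i, 60)),
                lapply(7:10, function(i) mk_prof(i, 70)))
  labels <- rep(c("CAS", "noCAS"), c(6, 4))
  cb <- compare_bins(profiles, labels, measures = c("hr", "pq"))
  expect_equal(nrow(cb), 16)
  expect_true(all(cb$p[cb$measure == "hr"] < 0.05))
})

test_that("logistic models recover injected effects and flag separation", {
  set.seed(11)
  n <- 2000
  df <- data.frame(age = rnorm(n, 60, 8), sex = rbinom(n, 1, 0.88),
                   beta_blocker = rbinom(n, 1, 0.2),
                   rate_limiting_ccb = rbinom(n, 1, 0.6),
                   feature = rnorm(n))
  lp <- -0.5 + 0.5 * df$feature + 0.01 * (df$age - 60)
  df$label <- rbinom(n, 1, plogis(lp))
  fit <- adjusted_logistic(df, "feature")
  expect_false(any(fit$separation))
  expect_equal(fit$adjusted$log_or, 0.5, tolerance = 0.1 / 0.5)
  expect_equal(fit$unadjusted$log_or, 0.5, tolerance = 0.15 / 0.5)

  df2 <- df; df2$label <- as.integer(df2$feature > 0)
  fit2 <- adjusted_logistic(df2, "feature")
  expect_true(fit2$separation["unadjusted"])
  expect_null(fit2$unadjusted)
})

test_that("resting 10-s selection picks the nearest-to-75 symptom-free window", {
  # Recording starting Mon 10:00; band windows on Tue and Wed 06:30-08:30
  iv <- data.frame(window_start = seq(0, 2.2 * 86400, by = 10))
  iv$hr_bpm <- 70
  iv$pq_ms <- 160; iv$qrs_ms <- 92; iv$qt_ms <- 400
  iv$usable <- TRUE
  h <- holterst:::clock_hour(iv$window_start, t_mon10)
  d <- as.Date(t_mon10 + iv$window_start, tz = "UTC")
  tue <- d == as.Date("2024-03-12"); wed <- d == as.Date("2024-03-13")
  band <- h >= 6.5 & h < 8.5
  iv$hr_bpm[wed & band] <- 71
  i3 <- which(wed & band)[c(10, 20, 30)]
  iv$hr_bpm[i3] <- c(71, 74.8, 78)
  sel <- select_resting_10s(iv, NULL, t_mon10)
  expect_equal(sel$hr_bpm, 74.8)
  expect_equal(sel$date, as.Date("2024-03-13"))
  expect_equal(sel$qtc_ms, qtc_bazett(400, 60000 / 74.8))

  # preferred day (Wed) has no usable band windows: falls back to Tuesday
  iv2 <- iv; iv2$usable[wed & band] <- FALSE
  iv2$hr_bpm[which(tue & band)[5]] <- 74.9
  sel2 <- select_resting_10s(iv2, NULL, t_mon10)
  expect_equal(sel2$date, as.Date("2024-03-12"))
  expect_equal(sel2$hr_bpm, 74.9)

  # exact ties break to the earliest window
  iv3 <- iv
  iv3$hr_bpm[which(wed & band)[c(12, 40)]] <- 75
  sel3 <- select_resting_10s(iv3, NULL, t_mon10)
  expect_equal(sel3$segment_start, iv3$window_start[which(wed & band)[12]])

  # a symptom within 15 min disqualifies neighbouring windows
  best <- which(wed & band)[20]
  sym <- data.frame(patient_id = "P1",
                    timestamp = t_mon10 + iv$window_start[best] + 300,
                    type = "chest_pain", source = "diary")
  sel4 <- select_resting_10s(iv, sym, t_mon10)
  expect_false(isTRUE(all.equal(sel4$segment_start,
                                iv$window_start[best])))

  # no candidate anywhere: absent with a message
  iv5 <- iv; iv5$usable[] <- FALSE
  expect_message(sel5 <- select_resting_10s(iv5, NULL, t_mon10),
                 "no resting")
  expect_null(sel5)
})

test_that("Bazett correction has its closed-form values and monotonicity", {
  expect_equal(qtc_bazett(400, 1000), 400)
  expect_equal(qtc_bazett(405, 800), 452.8038, tolerance = 1e-6)
  expect_equal(qtc_bazett(390, 1210), 354.5455, tolerance = 1e-6)
  rr <- seq(600, 1400, by = 100)
  expect_true(all(diff(qtc_bazett(400, rr)) < 0))
  expect_error(qtc_bazett(400, 0), "positive")
  expect_true(qtc_prolonged(461, "F"))
  expect_false(qtc_prolonged(455, "F"))
  expect_true(qtc_prolonged(455, "M"))
})

test_that("empirical power tracks the Welch noncentral-t formula", {
  # 33 vs 9, shift 5, SDs 5: Welch df 12.72, power 0.690
  se2 <- 25 / 33 + 25 / 9
  df <- se2^2 / ((25 / 33)^2 / 32 + (25 / 9)^2 / 8)
  ncp <- 5 / sqrt(se2); tc <- qt(0.975, df)
  pow <- 1 - pt(tc, df, ncp) + pt(-tc, df, ncp)
  set.seed(99)
  rej <- mean(replicate(800, compare_two_samples(
    rnorm(33, 60, 5), rnorm(9, 65, 5))$p < 0.05))
  expect_equal(rej, pow, tolerance = 0.05 / pow)
})
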