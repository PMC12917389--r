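# Median beats, the heart-rate-matched baseline library, and ST / T-wave
# deviation measurement.

# convenience: a 12-lead median beat whose content we control per lead over
# ms windows relative to QRS onset; qrs_off 90 ms, t_off 400 ms
flat_beat <- function(edit = NULL, hr = 60) {
  w <- matrix(0, length(holterst:::MB_T_MS), 12,
              dimnames = list(NULL, HOLTER_LEADS))
  t <- holterst:::MB_T_MS
  if (!is.null(edit)) for (e in edit)
    w[t >= e$lo & t <= e$hi, e$lead] <- w[t >= e$lo & t <= e$hi, e$lead] +
      if (is.function(e$v)) e$v(t[t >= e$lo & t <= e$hi]) else e$v
  median_beat(w, hr_bpm = hr, qrs_off_ms = 90, t_off_ms = 400, n_beats = 5)
}

test_that("median over identical beats reproduces the beat and suppresses spikes", {
  s <- clean_spec(201, hr = 60, rr_jitter_sd = 0, noise_sd = 0,
                  wander_amp = 0, beat_jitter = 0)
  g <- generate_recording(s, duration_s = 120)
  ann <- delineate(g$recording, detect_beats(g$recording))
  mbs <- median_beats(g$recording, ann)
  mb <- mbs$beats[[which(mbs$segments$has_beat)[2]]]
  # identical beats: the median beat equals any single aligned beat
  q <- round(ann$qrs_on[ann$class == "sinus"][15] * 200) + 1
  rel <- round(holterst:::MB_T_MS * 200 / 1000)
  single <- g$recording$signal[q + rel, ]
  expect_lt(max(abs(mb$wave - single)), 1e-5)

  # one corrupted beat out of >=5 cannot move the median by more than noise
  sig2 <- g$recording$signal
  k <- round(ann$r_peak[17] * 200)
  sig2[(k - 40):(k + 40), ] <- sig2[(k - 40):(k + 40), ] + 2.5
  rec2 <- ecg_recording(sig2, 200, g$recording$start_time)
  ann2 <- delineate(rec2, detect_beats(rec2))
  mbs2 <- median_beats(rec2, ann2)
  s17 <- floor(ann$r_peak[17] / 10) + 1
  if (mbs2$segments$has_beat[s17] && mbs$segments$has_beat[s17])
    expect_lt(max(abs(mbs2$beats[[s17]]$wave - mbs$beats[[s17]]$wave)),
              0.01)
})

test_that("alternating +a/-a corruption at one sample leaves the odd-count median unmoved", {
  w0 <- flat_beat()
  waves <- lapply(1:5, function(i) {
    w <- w0$wave
    w[50, "V2"] <- w[50, "V2"] + c(0.2, -0.2, 0.2, -0.2, 0)[i]
    w
  })
  med <- apply(simplify2array(waves), c(1, 2), median)
  expect_equal(unname(med[50, "V2"]), 0)
})

test_that("stationary recording populates exactly the matching 5-bpm bin", {
  s <- clean_spec(211, hr = 60, rr_jitter_sd = 5)
  g <- generate_recording(s, duration_s = 900)
  ps <- process_recording(g$recording)
  lib <- ps$baseline
  pop <- which(!vapply(lib$beats, is.null, logical(1)))
  expect_equal(lib$bins$lo[pop], 57.5)
  expect_equal(lib$bins$hi[pop], 62.5)
  # baseline matches the generating template closely (clean signal)
  tpl <- morphology_template(pq = 160, qrs = 92, qt = 445)
  bb <- lib$beats[[pop]]
  common <- which(bb$t_ms >= -150 & bb$t_ms <= 380)
  # allow a constant (possibly fractional-sample) alignment offset between
  # the delineator's QRS-onset convention and the template clock; the
  # residual reflects sub-sample beat-placement smearing at 200 Hz
  rms <- min(vapply(seq(-5, 5, 0.25), function(sh) {
    tv <- approx(tpl$t_ms, tpl$wave[, "II"], xout = bb$t_ms[common] + sh)$y
    sqrt(mean((bb$wave[common, "II"] - tv)^2, na.rm = TRUE))
  }, numeric(1)))
  expect_lt(rms, 0.01)
})

test_that("a heart-rate sweep populates many bins; short recordings fail", {
  # synthetic median-beat set sweeping 50 -> 100 bpm
  mb_list <- lapply(seq(50, 100, length.out = 120), function(hr)
    flat_beat(hr = hr))
  seg <- data.frame(segment_start = (0:119) * 10,
                    hr_bpm = seq(50, 100, length.out = 120),
                    n_beats = 8, qrs_off_ms = 90, t_off_ms = 400,
                    has_beat = TRUE)
  mbs <- structure(list(segments = seg, beats = mb_list, window = 10),
                   class = "median_beats")
  lib <- build_baseline_library(mbs)
  expect_gte(sum(!vapply(lib$beats, is.null, logical(1))), 8)

  s <- clean_spec(221, hr = 60)
  g <- generate_recording(s, duration_s = 30.5)
  expect_error(process_recording(g$recording), "insufficient baseline")
})

test_that("ST deviation reads a constructed -0.05 mV V5 shift exactly", {
  base <- flat_beat()
  segb <- flat_beat(list(list(lead = "V5", lo = 90, hi = 240, v = -0.05)))
  d <- st_deviation(segb, base)
  expect_equal(unname(d["V5"]), -0.05)
  expect_equal(unname(d[setdiff(HOLTER_LEADS, "V5")]),
               rep(0, 11))
  expect_equal(unname(st_deviation(base, base)), rep(0, 12))
})

test_that("isoelectric alignment cancels whole-beat offsets", {
  base <- flat_beat()
  shifted <- flat_beat(list(list(lead = "V3", lo = -200, hi = 450,
                                 v = 0.08)))
  expect_equal(unname(st_deviation(shifted, base)["V3"]), 0)
})

test_that("T-wave deviations follow constructed scalings and inversions", {
  tshape <- function(amp) function(t) amp * sin(pi * (t - 240) / 160)^2
  base <- flat_beat(list(list(lead = "V4", lo = 240, hi = 400,
                              v = tshape(0.30))))
  half <- flat_beat(list(list(lead = "V4", lo = 240, hi = 400,
                              v = tshape(0.15))))
  td <- t_wave_deviation(half, base)
  expect_equal(unname(td$tmax["V4"]), -0.15)
  expect_equal(unname(td$tmin["V4"]), 0)

  # inversion of a biphasic T: both deviations equal -(max + min)
  bi <- function(s) function(t) s * (0.2 * sin(pi * (t - 240) / 160)^2 -
                                       0.3 * sin(pi * (t - 240) / 160)^6)
  b1 <- flat_beat(list(list(lead = "V2", lo = 240, hi = 400, v = bi(1))))
  b2 <- flat_beat(list(list(lead = "V2", lo = 240, hi = 400, v = bi(-1))))
  i <- holterst:::MB_T_MS >= 170 & holterst:::MB_T_MS <= 400
  w <- b1$wave[i, "V2"]
  td2 <- t_wave_deviation(b2, b1)
  expect_equal(unname(td2$tmin["V2"]), -(max(w) + min(w)))
  expect_equal(unname(td2$tmax["V2"]), -(max(w) + min(w)))
})

test_that("swapping segment and baseline negates every deviation", {
  set.seed(5)
  for (rep in 1:5) {
    mk <- function() {
      w <- matrix(rnorm(length(holterst:::MB_T_MS) * 12, 0, 0.1),
                  ncol = 12, dimnames = list(NULL, HOLTER_LEADS))
      median_beat(w, 60, 90, 400, 5)
    }
    a <- mk(); b <- mk()
    expect_equal(st_deviation(a, b), -st_deviation(b, a))
    ta <- t_wave_deviation(a, b); tb <- t_wave_deviation(b, a)
    expect_equal(ta$tmin, -tb$tmin)
    expect_equal(ta$tmax, -tb$tmax)
  }
})

test_that("null recording gives deviations centred at zero", {
  s <- clean_spec(231, hr = 62)
  g <- generate_recording(s, duration_s = 900)
  ps <- process_recording(g$recording)
  expect_lt(abs(mean(ps$deviations$st, na.rm = TRUE)), 0.005)
})

test_that("heart-rate matching never reaches beyond 10 bpm", {
  mb_list <- lapply(1:15, function(i) flat_beat(hr = 60))
  seg <- data.frame(segment_start = (0:14) * 10, hr_bpm = 60, n_beats = 8,
                    qrs_off_ms = 90, t_off_ms = 400, has_beat = TRUE)
  mbs <- structure(list(segments = seg, beats = mb_list, window = 10),
                   class = "median_beats")
  lib <- build_baseline_library(mbs)
  expect_equal(match_baseline_bin(lib, 60), 5L)
  expect_equal(match_baseline_bin(lib, 69), 5L)    # within 10 bpm
  expect_true(is.na(match_baseline_bin(lib, 75)))  # 15 bpm away
  seg75 <- flat_beat(hr = 75)
  expect_true(all(is.na(st_deviation(seg75, lib))))
})

test_that("an injected sub-cutoff episode still leaves a measurable deviation", {
  s <- clean_spec(241, hr = 60)
  ep <- list(episode_spec("st_offset", -0.035, c("V5", "V6"),
                          start = 500, duration_s = 150, ramp_s = 10))
  g <- generate_recording(s, duration_s = 1500, episodes = ep)
  ps <- process_recording(g$recording)
  dev <- ps$deviations
  during <- dev$segment_start >= 520 & dev$segment_start < 630
  expect_gte(mean(-dev$st[during, "V5"], na.rm = TRUE), 0.030)
  expect_gte(mean(-dev$st[during, "V6"], na.rm = TRUE), 0.030)
})
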