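# Independent oracles, deliberately naive: no shared code with the package
# implementations they check.

# Brute-force ischemia event scanner: explicit loops over segments and
# contiguous pairs, no run-length shortcuts.
brute_force_events <- function(dev, parameter, cutoff,
                               rule = "pair_stable", min_run = 3) {
  mag <- switch(parameter,
                st_deviation = abs(dev$st),
                st_elevation = dev$st,
                st_depression = -dev$st,
                tmin_deviation = abs(dev$tmin),
                tmax_deviation = abs(dev$tmax))
  S <- nrow(mag)
  pairs <- contiguous_pairs()
  covered <- rep(FALSE, S)
  runs <- list()   # per-pair qualifying stretches of length >= min_run
  for (p in seq_len(nrow(pairs))) {
    a <- which(dev$leads == pairs[p, 1])
    b <- which(dev$leads == pairs[p, 2])
    q <- rep(FALSE, S)
    for (s in seq_len(S)) {
      va <- mag[s, a]; vb <- mag[s, b]
      q[s] <- dev$usable[s] && !is.na(va) && !is.na(vb) &&
        va >= cutoff && vb >= cutoff
    }
    if (rule == "pair_stable") {
      s <- 1
      while (s <= S) {
        if (q[s]) {
          e <- s
          while (e < S && q[e + 1]) e <- e + 1
          if (e - s + 1 >= min_run) {
            covered[s:e] <- TRUE
            runs[[length(runs) + 1]] <- list(pair = p, s = s, e = e)
          }
          s <- e + 1
        } else s <- s + 1
      }
    } else {
      runs[[length(runs) + 1]] <- list(pair = p, q = q)
    }
  }
  if (rule == "any_pair") {
    anyq <- rep(FALSE, S)
    for (s in seq_len(S))
      for (r in runs) if (r$q[s]) anyq[s] <- TRUE
    runs2 <- list()
    s <- 1
    while (s <= S) {
      if (anyq[s]) {
        e <- s
        while (e < S && anyq[e + 1]) e <- e + 1
        if (e - s + 1 >= min_run) {
          covered[s:e] <- TRUE
          for (r in seq_along(runs))
            if (any(runs[[r]]$q[s:e]))
              runs2[[length(runs2) + 1]] <- list(pair = r, s = s, e = e)
        }
        s <- e + 1
      } else s <- s + 1
    }
    runs <- runs2
  }
  # events = maximal stretches of covered segments
  out <- NULL
  s <- 1
  while (s <= S) {
    if (covered[s]) {
      e <- s
      while (e < S && covered[e + 1]) e <- e + 1
      leads <- character(0)
      for (r in runs)
        if (!is.null(r$s) && r$s <= e && r$e >= s)
          leads <- c(leads, pairs[r$pair, ])
      leads <- unique(leads)
      leads <- leads[order(match(leads, HOLTER_LEADS))]
      jc <- match(leads, dev$leads)
      out <- rbind(out, data.frame(
        start = dev$segment_start[s],
        end = dev$segment_start[e] + dev$seg_len,
        duration_s = (e - s + 1) * dev$seg_len,
        leads = paste(leads, collapse = ","),
        peak_mv = max(mag[s:e, jc], na.rm = TRUE),
        stringsAsFactors = FALSE))
      s <- e + 1
    } else s <- s + 1
  }
  if (is.null(out))
    out <- data.frame(start = numeric(0), end = numeric(0),
                      duration_s = numeric(0), leads = character(0),
                      peak_mv = numeric(0), stringsAsFactors = FALSE)
  out
}

# random small deviation grid for oracle-equivalence checks
random_dev_grid <- function(S = 20, seed = 1) {
  set.seed(seed)
  vals <- c(-0.06, -0.045, -0.03, 0, 0.03, 0.05)
  mk <- function() matrix(sample(vals, S * 12, replace = TRUE,
                                 prob = c(.1, .15, .15, .4, .1, .1)), S, 12)
  deviation_series((0:(S - 1)) * 10, mk(), mk(), mk(),
                   usable = runif(S) > 0.1)
}

# Wilson interval by the quadratic-root derivation (independent route)
wilson_oracle <- function(k, n, conf = 0.95) {
  z <- qnorm(1 - (1 - conf) / 2)
  p <- k / n
  # roots of (p - pi)^2 * n = z^2 * pi * (1 - pi)
  a <- n + z^2
  b <- -(2 * n * p + z^2)
  cc <- n * p^2
  disc <- sqrt(b^2 - 4 * a * cc)
  sort(c((-b - disc) / (2 * a), (-b + disc) / (2 * a)))
}

# Fisher two-sided p by explicit enumeration with binomial coefficients
fisher_oracle <- function(tp, fp, fn, tn) {
  m <- tp + fn; n <- fp + tn; k <- tp + fp
  support <- max(0, k - n):min(k, m)
  lp <- lchoose(m, support) + lchoose(n, k - support) - lchoose(m + n, k)
  probs <- exp(lp)
  p_obs <- exp(lchoose(m, tp) + lchoose(n, k - tp) - lchoose(m + n, k))
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

# clean, stationary waveform spec for recovery tests
clean_spec <- function(seed, hr = 60, ...) {
  args <- utils::modifyList(
    list(seed = seed, hr_mesor = hr, hr_amp = 0, rr_jitter_sd = 10,
         noise_sd = 0.008, wander_amp = 0.05, artifact_frac = 0,
         shower_gap_min = 0, episode_rate = 0, days = 3),
    list(...))
  do.call(patient_spec, args)
}
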