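# Diagnostic-accuracy layer: 2x2 tables with Wilson-interval metrics,
# Fisher exact tests, bootstrap ROC/AUC, and sweep-curve assembly.

#' Cross-tabulate test flags against disease labels
#'
#' @param flags logical test positivity per patient.
#' @param labels logical (or coercible) disease status per patient, `TRUE`
#'   = diseased.
#' @param rule free-text description of the positivity rule.
#' @return list of class `"two_by_two"`: `tp`, `fp`, `fn`, `tn`, `rule`.
#' @export
two_by_two <- function(flags, labels, rule = "") {
  stopifnot(length(flags) == length(labels), length(flags) > 0)
  if (anyNA(flags) || anyNA(labels)) stop("flags and labels must be complete")
  flags <- as.logical(flags); labels <- as.logical(labels)
  structure(list(tp = sum(flags & labels), fp = sum(flags & !labels),
                 fn = sum(!flags & labels), tn = sum(!flags & !labels),
                 rule = rule),
            class = "two_by_two")
}

#' Build a 2x2 table directly from counts
#' @param tp,fp,fn,tn non-negative counts.
#' @param rule positivity rule description.
#' @return a `"two_by_two"`.
#' @export
two_by_two_table <- function(tp, fp, fn, tn, rule = "") {
  stopifnot(tp >= 0, fp >= 0, fn >= 0, tn >= 0)
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn, rule = rule),
            class = "two_by_two")
}

#' @export
print.two_by_two <- function(x, ...) {
  cat(sprintf("<two_by_two> TP %d  FP %d  FN %d  TN %d\n",
              x$tp, x$fp, x$fn, x$tn))
  invisible(x)
}

#' Wilson score confidence interval for a binomial proportion
#'
#' @param successes,n counts, `0 <= successes <= n`, `n > 0`.
#' @param conf confidence level.
#' @return numeric `c(low, high)`.
#' @export
wilson_ci <- function(successes, n, conf = 0.95) {
  if (n <= 0) stop("n must be positive")
  stopifnot(successes >= 0, successes <= n)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- successes / n
  center <- (p + z^2 / (2 * n)) / (1 + z^2 / n)
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
  c(low = max(0, center - half), high = min(1, center + half))
}

#' Sensitivity, specificity, PPV and NPV with Wilson intervals
#'
#' Metrics with a zero denominator are returned as `NA` with an `NA`
#' interval.
#'
#' @param t a `"two_by_two"`.
#' @param conf confidence level for the Wilson intervals.
#' @return data.frame: metric, estimate, low, high, k, n, method.
#' @export
diagnostic_metrics <- function(t, conf = 0.95) {
  stopifnot(inherits(t, "two_by_two"))
  defs <- list(sensitivity = c(t$tp, t$tp + t$fn),
               specificity = c(t$tn, t$tn + t$fp),
               ppv = c(t$tp, t$tp + t$fp),
               npv = c(t$tn, t$tn + t$fn))
  rows <- lapply(names(defs), function(m) {
    k <- defs[[m]][1]; n <- defs[[m]][2]
    if (n == 0)
      return(data.frame(metric = m, estimate = NA_real_, low = NA_real_,
                        high = NA_real_, k = k, n = n, method = "wilson",
                        stringsAsFactors = FALSE))
    w <- wilson_ci(k, n, conf)
    data.frame(metric = m, estimate = k / n, low = w[1], high = w[2],
               k = k, n = n, method = "wilson", stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Two-sided Fisher exact test for a 2x2 table
#'
#' Conditional on the margins, sums hypergeometric probabilities less than
#' or equal to (within a 1e-7 relative tolerance) that of the observed
#' table.
#'
#' @param t a `"two_by_two"`.
#' @return two-sided p-value.
#' @export
fisher_exact <- function(t) {
  stopifnot(inherits(t, "two_by_two"))
  m <- t$tp + t$fn        # diseased
  n <- t$fp + t$tn        # non-diseased
  k <- t$tp + t$fp        # test-positive margin
  if (m + n == 0) return(NA_real_)
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(t$tp, m, n, k)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Rank-based AUC with a stratified bootstrap confidence interval
#'
#' AUC by the Mann-Whitney formulation with half credit for ties; the CI
#' comes from the 2.5th/97.5th percentiles of `B` bootstrap resamples drawn
#' with replacement within each class (stratified, preserving the group
#' imbalance).
#'
#' @param score numeric score per patient (higher = more disease-like).
#' @param labels logical disease status.
#' @param B bootstrap replicates.
#' @param seed integer seed for the resampling.
#' @param conf confidence level.
#' @return list of class `"roc_result"`: `auc`, `ci`, `curve`
#'   (data.frame threshold, sensitivity, one_minus_specificity), `B`,
#'   `seed`.
#' @export
roc_auc_bootstrap <- function(score, labels, B = 1000, seed = 1L,
                              conf = 0.95) {
  labels <- as.logical(labels)
  stopifnot(length(score) == length(labels))
  if (!any(labels) || all(labels)) stop("both classes must be present")
  auc_of <- function(s, l) {
    r <- rank(s)
    n1 <- sum(l); n0 <- sum(!l)
    (sum(r[l]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }
  auc <- auc_of(score, labels)
  pos <- which(labels); neg <- which(!labels)
  # seed the resampling locally; restore the caller's RNG stream afterwards
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed))
      assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(seed)
  reps <- vapply(seq_len(B), function(b) {
    i <- c(sample(pos, length(pos), replace = TRUE),
           sample(neg, length(neg), replace = TRUE))
    auc_of(score[i], labels[i])
  }, numeric(1))
  a <- (1 - conf) / 2
  ci <- stats::quantile(reps, c(a, 1 - a), names = FALSE, type = 7)
  thr <- sort(unique(c(-Inf, score, Inf)), decreasing = TRUE)
  curve <- data.frame(
    threshold = thr,
    sensitivity = vapply(thr, function(x) mean(score[labels] >= x),
                         numeric(1)),
    one_minus_specificity = vapply(thr, function(x)
      mean(score[!labels] >= x), numeric(1)))
  structure(list(auc = auc, ci = ci, curve = curve, B = B, seed = seed),
            class = "roc_result")
}

#' Assemble plot-ready sweep curves
#'
#' Tidies a [threshold_sweep()] result into one row per cutoff and group
#' with Wilson bands, a significance mark where the per-cutoff Fisher p is
#' below `alpha`, and the 0.1 mV consensus reference cutoff.
#'
#' @param sweep a `"sweep_result"`.
#' @param alpha significance level for the marks.
#' @param reference_mv reference cutoff carried in the output.
#' @return data.frame: parameter, cutoff, group, n_pos, n, prop, wilson_lo,
#'   wilson_hi, fisher_p, significant, reference_mv.
#' @export
assemble_sweep_curves <- function(sweep, alpha = 0.05, reference_mv = 0.1) {
  tb <- sweep$table
  tb$significant <- !is.na(tb$fisher_p) & tb$fisher_p < alpha
  tb$parameter <- sweep$parameter
  tb$reference_mv <- reference_mv
  tb[, c("parameter", "cutoff", "group", "n_pos", "n", "prop",
         "wilson_lo", "wilson_hi", "fisher_p", "significant",
         "reference_mv")]
}
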