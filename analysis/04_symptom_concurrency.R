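#!/usr/bin/env Rscript
# Merge the diary and button streams, count acute symptoms, and score their
# concurrency (+/-30 min) with ST-depression events at both study cutoffs.

library(holterst)

seed <- 20240311L
outdir <- "results"
co <- fixture_cohort(seed = seed)

rates <- do.call(rbind, lapply(co$patients, function(p) {
  m <- merge_symptoms(p$log)
  days <- p$data$span_s / 86400
  data.frame(patient_id = p$patient_id, label = p$label,
             diary_per_day = sum(p$log$source == "diary") / days,
             button_per_day = sum(p$log$source == "button") / days,
             merged_per_day = nrow(m) / days)
}))
utils::write.csv(rates, file.path(outdir, "symptom_rates.csv"),
                 row.names = FALSE)
cat(sprintf("median merged symptoms/day: %.1f (diary %.1f, button %.1f)\n",
            median(rates$merged_per_day), median(rates$diary_per_day),
            median(rates$button_per_day)))

for (cutoff in c(0.035, 0.040)) {
  cc <- cohort_concurrency(co, "st_depression", cutoff)
  utils::write.csv(cc, file.path(outdir, sprintf("concurrency_%04.0f.csv",
                                                 cutoff * 1000)),
                   row.names = FALSE)
  with_sym <- cc[cc$n_acute > 0, ]
  cat(sprintf(
    "cutoff %.3f mV: %d/%d symptomatic patients with >=1 concurrent symptom; median %% concurrent %.0f%%\n",
    cutoff, sum(with_sym$flag_any_concurrent), nrow(with_sym),
    median(with_sym$pct_concurrent)))
}
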