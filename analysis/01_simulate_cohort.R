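#!/usr/bin/env Rscript
# Simulate the demonstration cohort (4 CAS / 2 noCAS, 2 days each) and one
# waveform-level example patient.  Writes the symptom logs, ground truth and
# the example recording (WFDB) under results/.  Later scripts regenerate the
# same cohort deterministically from the seed instead of reloading it.

library(holterst)

seed <- 20240311L
outdir <- "results"
dir.create(file.path(outdir, "cohort"), recursive = TRUE,
           showWarnings = FALSE)

co <- fixture_cohort(seed = seed)
cat(sprintf("simulated %d patients (%d CAS / %d noCAS), 2 days each\n",
            length(co$patients), co$n_cas, co$n_nocas))

for (p in co$patients) {
  write_symptom_log(p$log, file.path(outdir, "cohort",
                                     paste0(p$patient_id, "_symptoms.csv")))
  write_truth(p$truth, file.path(outdir, "cohort",
                                 paste0(p$patient_id, "_truth.json")))
  utils::write.csv(p$data$interval_series,
                   file.path(outdir, "cohort",
                             paste0(p$patient_id, "_intervals.csv")),
                   row.names = FALSE)
}

truth_pos <- vapply(co$patients, function(p) p$truth$burden_state == 1,
                    logical(1))
cat("burden-positive by ground truth:",
    paste(vapply(co$patients, `[[`, "", "patient_id")[truth_pos],
          collapse = ", "), "\n")

# one waveform patient (20 min at 200 Hz) with a known ST-depression episode
sp <- patient_spec(seed = seed + 99, hr_mesor = 62, hr_amp = 0,
                   rr_jitter_sd = 10, artifact_frac = 0,
                   shower_gap_min = 0, episode_rate = 0)
ep <- list(episode_spec("st_offset", -0.05, c("V4", "V5"),
                        start = 600, duration_s = 120))
g <- generate_recording(sp, duration_s = 1200, episodes = ep,
                        patient_id = "W001")
write_wfdb(g$recording, "W001", file.path(outdir, "cohort"))
write_truth(g$truth[c("episodes", "gaps", "span_s")],
            file.path(outdir, "cohort", "W001_truth.json"))
cat("wrote waveform example W001 (1200 s, one -0.05 mV episode in V4/V5)\n")
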