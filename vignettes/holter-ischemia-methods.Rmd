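---
title: "Methods: ischemia detection and circadian profiling from 12-lead Holter ECG"
author: "holterst"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ischemia detection and circadian profiling from 12-lead Holter ECG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(holterst)
```

## The problem

Patients with angina and non-obstructive coronary arteries (ANOCA) often
suffer coronary artery spasm (CAS): transient vasoconstriction causing
ischemia that an in-hospital resting ECG rarely captures. Multi-day
ambulatory 12-lead Holter monitoring with symptom tracking offers a
non-invasive window on these events. This package implements the full
analysis chain for such recordings: beat-level reduction of the waveform,
patient-specific heart-rate-matched median-beat ST/T deviation measurement,
rule-based ischemia event detection across a cutoff sweep, daily burden
normalization, symptom concurrency, circadian conduction-time profiles, a
standardized resting 10-s assessment, and a diagnostic-accuracy layer.

Because no recordings of this kind are publicly deposited, the package
ships a synthetic cohort generator whose ground truth makes every
downstream claim testable by parameter recovery.

## The reduction chain

**Beat detection and delineation.** QRS complexes are found on lead II by a
difference filter, squaring, 150-ms moving-window integration, an adaptive
threshold, and a 250-ms refractory rule. Before delineation the lead is
detrended with a 0.6-s running-median baseline filter (removing
electrode-motion wander that otherwise defeats amplitude thresholds). QRS
onset/offset come from amplitude thresholds on the raw detrended signal
(2% / 5% of the local R amplitude); P and T boundaries from a 2.5%
threshold on a 25-ms smoothed signal. Beats are classified non-sinus when
QRS exceeds 120 ms or RR deviates more than 20% from the local median RR
(running window of 9); beats whose fiducials cannot be resolved in
physiologic order are flagged artifact, not dropped. These choices define
an open delineation stack; its conformance criterion is recovery of the
generator's per-window medians within ±10 ms (PQ/QRS/QT) and ±1 bpm.

**Per-window reduction.** The recording is reduced on a fixed 10-s grid
aligned to the recording clock and continuous across gaps: median heart
rate (60000 / median RR) and median PQ/QRS/QT over sinus beats, absent when
fewer than 3 sinus beats support the window. SDNN (sample SD, denominator
N−1, of sinus-to-sinus intervals) is computed per 5-min window and reported
only with ≥ 30 NN intervals — both floors are conventional HRV practice. A
window is unusable iff it overlaps an annotated gap, its artifact-beat
fraction exceeds 0.3, or amplitude saturates (≥ 5 mV).

**Median beats and the baseline library.** Within each usable 10-s segment
the per-lead median beat is the sample-wise median across QRS-onset-aligned
beats (window −200 to +450 ms). The patient's baseline library bins
segments by heart rate into 5-bpm bins centred on 40, 45, …, 140 bpm; a bin
is populated when ≥ 10 segments contribute, and its baseline is the
sample-wise median of the contributing segment median beats after
isoelectric alignment (each beat is first referenced to its own PQ level;
without this, slow baseline offsets leak into the pooled median — we
observed ~0.01 mV of spurious shift). The baseline uses the whole
recording; with frequent episodes this slightly dilutes measured
deviations, a deliberate trade against bin support.

**Deviation measurement.** The ST deviation of a segment is the mean
amplitude over J+40..J+80 ms (J point = QRS offset) minus the same quantity
of the matched baseline beat, both referenced to their PQ isoelectric level
(−30..−10 ms before QRS onset). T-wave deviations are the min/max amplitude
over QRS offset + 80 ms to T offset, likewise referenced. A segment is
matched to its own heart-rate bin, or the nearest populated bin within
±10 bpm; otherwise the deviation is absent. The mean-over-window ST measure
is robust at 200 Hz; by construction deviations are anti-symmetric under
swapping segment and baseline.

## The ischemia rule

An ischemia event for a parameter (ST deviation, elevation, depression,
min/max T-wave deviation) and cutoff requires the deviation to exceed the
cutoff in **at least two contiguous leads for at least 30 s**. Contiguity
follows the standard anatomical chains (inferior II–III–aVF, lateral
I–aVL–V5–V6, anterior V1–V2–V3–V4, with V4–V5 linking chains). Because
deviations live on the 10-s grid, "at least 30 s" means ≥ 3 consecutive
qualifying usable segments; unusable segments break a run. The default
reading is *pair-stable*: the same contiguous pair must qualify throughout
a run (the alternative — some pair per segment — is exposed as
`rule = "any_pair"`). Overlapping or touching runs from different pairs
merge into one event whose lead set is the union of contributing pairs.
Both readings are verified against a brute-force per-segment scanner.

Burden divides total event duration by usable recording duration and
rescales to seconds per 24 h; the positivity flag is ≥ 60 s/day. Burden
flags are monotone non-increasing in the cutoff, which the sweep over
0–0.5 mV (step 0.005 mV, resolving the 0.035/0.040 mV distinction) relies
on. Symptom concurrency counts acute symptoms (chest pain, dyspnea) whose
closed ±30-min window overlaps any event; patients with no acute symptoms
carry an absent percentage and a negative flag in the 2×2 tables. Diary
and button reports of the same type within 10 min merge into one symptom,
keeping the diary timestamp.

## Circadian and resting assessments

Days run noon-to-noon on the recording's clock and qualify with ≥ 50%
usable windows. Profiles are medians per 3-h clock bin (8 bins from
midnight), requiring ≥ 10 usable windows per bin; group summaries report
the median and 2.5th/97.5th percentiles across patients. Per-bin group
tests use Welch's t-test when Shapiro–Wilk keeps p > 0.05 in both groups,
else Mann–Whitney (constant or tiny samples route to Mann–Whitney; two
identical constant groups give p = 1 by convention). Features with group
differences feed logistic models, unadjusted and adjusted for age, sex,
beta-blocker and rate-limiting calcium-channel-blocker use, with Wald
intervals; separation or non-convergence is flagged with no estimate.

The resting 10-s assessment picks, among usable symptom-free (±15 min)
windows between 06:30 and 08:30 on the preferred day (falling back one
day), the window with heart rate closest to 75 bpm, ties to the earliest —
nearest-match selection with the achieved heart rate reported, which is
what makes reported medians sit at essentially exactly 75 bpm. QTc uses
Bazett (QT/√RR, RR in seconds); the prolonged-QTc convention is
≥ 460 ms (women) / ≥ 450 ms (men), configurable.

## Diagnostic layer

2×2 tables cross test flags with CAS status; sensitivity, specificity, PPV
and NPV carry 95% Wilson score intervals (zero denominators yield absent
metrics). Group differences per cutoff use the two-sided conditional
Fisher exact test (hypergeometric tail sum, verified against exhaustive
enumeration). AUC uses the rank (Mann–Whitney) formulation with half
credit for ties; its CI comes from 1000 stratified bootstrap resamples
(stratification preserves the cohort's roughly 33:9 imbalance), seeded and
reproducible. The AUC score for the burden analysis is the continuous
normalized burden (s/day): a binary flag cannot produce intermediate AUC
values, so the continuous burden is the defensible choice, with the flag
variant available. No multiplicity correction is applied — the sweep is
exploratory by design and outputs say so.

## The synthetic cohort

The generator has two tiers sharing one set of models:

* **Waveform tier** (`generate_recording()`): a full 200 Hz, 12-lead
  signal. Each beat is a sum of compact-support raised-cosine lobes
  (P, Q, R, S, T) whose supports end exactly at the nominal fiducials, so
  delineation error is measurable without convention mismatches. Beat-to-
  beat RR follows a circadian cosine (acrophase 15:00, nocturnal minimum
  03:00) plus RR jitter; QT follows Bazett from a per-patient QTc; PQ
  gains a nocturnal increment. Episodes add a ramped offset to the ST
  segment (or T lobe) of affected leads, so the injected amplitude equals
  the deviation the pipeline should read. Noise: white measurement noise,
  two-component baseline wander, Poisson artifact bursts (high-amplitude,
  truth-annotated), a daily 20-min electrode-off gap and 4-min battery
  changes every 48 h (zero-filled, annotated). Defaults leave roughly 80%
  of a recording usable.
* **Segment tier** (`simulate_segments()`): the same circadian, episode,
  symptom and usability models emitted directly on the 10-s grid
  (deviation noise: AR(1) across segments, lag-1 correlation 0.5, SD
  0.010 mV with a shared across-lead component). This tier exists because
  cohort-scale experiments (thousands of multi-day patients) are not
  tractable at 200 Hz × 12 leads; waveform↔segment consistency is itself
  under test via the recovery suite.

Group defaults encode the contrasts the pipeline must detect: CAS patients
have lower nocturnal heart rate (mesor 68, amplitude 8.5 vs 72/7.5 bpm),
longer PQ (165 + 15 ms nocturnal vs 148 + 8 ms), higher QTc (451 vs
440 ms) and a higher burden-positive probability (0.88 vs 0.44). A
burden-positive patient receives 2 episodes/day with ST-offset amplitudes
N(0.05, 0.02) mV floored at 0.045 and durations 90–300 s — centred where
the 0.035/0.040 mV cutoffs discriminate; burden-negative patients receive
sub-threshold 0.02 mV episodes. The deterministic episode count per
patient keeps the burden-positive state crisp, which is what the recovery
criterion measures. Symptoms: merged reports arrive at 2.9/day with
diary/button marginals 1.9/2.9 and 1.4/2.9 and minimal-overlap coupling
(both-streams probability 0.4/2.9) — the unique assignment consistent with
all three observed rates; each episode emits an acute symptom within
−10..+20 min of onset with probability 0.3. Per-episode spasm durations
and amplitudes are calibration choices, not estimates — the source cohort
reports none.

What the generator does **not** emulate: real beat-morphology variety
(bundle-branch blocks, axis shifts), atrial fibrillation, electrode
repositioning after showers, or drift in episode amplitude with medication
pauses. Passing recovery tests therefore demonstrates the pipeline's
correctness under its stated model, not clinical performance on real
recordings.

## Numerical choices and degenerate inputs

Windows are half-open and clock-aligned; 30-s minimum duration means three
full segments (no sub-segment timing, no bridging across unusable
segments). Cutoff comparisons are inclusive (≥), so cutoff 0 counts any
sustained non-missing deviation. Flatline or all-gap input yields an empty
annotation with a warning; fewer than 30 s of non-gap signal is an error.
A baseline library with no bin reaching 10 segments is an error
("insufficient baseline"). Wilson intervals are clamped to [0, 1]; Fisher
uses a 1 + 1e−7 relative tolerance when summing tail probabilities
(matching the conditional two-sided convention). All simulation is seeded;
per-patient seeds derive linearly from the master seed modulo 2^31.

At 200 Hz, beats fall at arbitrary sub-sample phases, so pooled median
beats slightly smooth steep QRS slopes; template-recovery RMS is ~0.01 mV
after optimal fractional alignment even on clean signal, while ST-window
recovery stays within ±0.005 mV.

## Problem sizes used by the test and acceptance runs

Chosen as the package's own validation design: cohort recovery of the
0.88/0.44 burden-positive proportions uses 1000 patients/arm × 1 day at
segment tier (binomial SE ≈ 0.01, against a ±0.03 criterion); the null
false-positive rate uses 300 episode-free patients; test-choice type-I
calibration uses 1500 replicate 33-vs-9 cohorts; the null AUC uses 1000
replicate cohorts; waveform recovery uses 10–25 min recordings; the
demonstration cohort is 4 CAS + 2 noCAS patients × 2 days.

## Known limitations

Cohort-level results from the source setting (e.g., an AUC near 0.65, or
specific nocturnal group means) require the real recordings and are out of
scope; the synthetic recovery suite substitutes for them. EDF input is not
implemented (WFDB format 16 is the native interchange); the delineator is
tuned for adult sinus-rhythm morphology at 200 Hz; SDNN is the only HRV
measure; QT correction is Bazett only.
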