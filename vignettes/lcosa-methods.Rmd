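---
title: "Screening for obstructive sleep apnea from load-cell bed signals: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening for obstructive sleep apnea from load-cell bed signals: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the measurement

Obstructive sleep apnea (OSA) is diagnosed from the apnea–hypopnea index
(AHI): the average number of apnea and hypopnea events per hour of sleep.
Clinically, AHI < 5 events/h is normal, 5–15 is mild, and above 15 is
moderate-to-severe (moderate and severe are handled as one class here
because both are managed with CPAP). Polysomnography and wearable home
tests measure AHI accurately but obtrusively. An array of four load cells
under the mattress — two under the shoulders, two under the hips — records
breathing effort, the ballistocardiogram (the body's recoil from each
heartbeat), and gross movement without touching the sleeper. `lcosa`
implements a complete screening pipeline from such recordings to a
per-subject severity grade, together with the evaluation machinery used to
judge it against gold-standard scoring.

The pipeline does **not** detect individual apnea or hypopnea events. It
estimates the nightly AHI directly from the shape of the signal's spectrum,
and grades severity from that estimate.

## Signal path

1. **Combine.** The four channels are summed sample-by-sample
   (`combine_channels()`). Channel units are arbitrary; standardization
   later removes all gain.
2. **Band-pass.** The composite is demeaned and filtered to 0.05–5 Hz
   (`bandpass()`). The upper edge removes non-physiologic noise harmonics;
   the lower edge removes baseline drift while preserving the slowest
   analysis band (0.06–0.08 Hz). *Numerical choice:* the filter is realized
   as a zero-phase cascade — 2nd-order Butterworth high-pass at 0.05 Hz
   followed by 4th-order Butterworth low-pass at 5 Hz, each applied
   forward–backward. A single band-pass transfer function with a lower edge
   at 4·10⁻⁴ of Nyquist is numerically unstable in double precision under
   `filtfilt` (we observed outputs blowing up by ~70 orders of magnitude at
   order 8); the cascade has the same passband and is stable. Zero-phase
   filtering matters because phase distortion would corrupt the moment
   features.
3. **Standardize.** Zero mean, unit *population* standard deviation
   (`standardize()`). The population convention makes downstream spectral
   magnitudes exactly reproducible for a given input. A constant signal is
   a flat or disconnected sensor and raises a typed error.
4. **Spectrum.** A single full-length FFT of the whole (valid) signal
   (`magnitude_spectrum()`) — no Welch averaging, because the sub-band
   analysis needs the finest available frequency resolution. Signals
   shorter than 150 s are rejected so every 0.02 Hz sub-band spans at
   least 3 bins.
5. **Sub-band moments.** `[0, 5)` Hz is tiled with consecutive half-open
   0.02 Hz sub-bands anchored at 0 Hz, and the mean, variance, skewness
   and kurtosis of the Fourier-coefficient magnitudes are computed per band
   (`subband_moments()`). Conventions: adjusted Fisher–Pearson skewness
   (e1071 type 2) and excess kurtosis g₂ (e1071 type 1, normal → 0; this
   form stays defined at the 3-bin minimum occupancy where the adjusted
   form divides by zero). Zero-variance bands report 0 for both with a
   warning.
6. **Features.** Six moments drive the classifier (`extract_features()`):

   | feature | band (Hz) | statistic | stage |
   |---------|-----------|-----------|-------|
   | X1 | 0.06–0.08 | kurtosis | decision tree |
   | X2 | 0.36–0.38 | skewness | regression |
   | X3 | 0.96–0.98 | skewness | regression |
   | X4 | 1.18–1.20 | kurtosis | decision tree |
   | X5 | 1.40–1.42 | kurtosis | regression |
   | X6 | 1.68–1.70 | skewness | decision tree |

   These bands were originally chosen by ranking every band × statistic
   candidate by its one-way ANOVA F statistic against the three severity
   classes; `anova_select()` implements that procedure so the selection is
   reproducible on new cohorts.

**Windowing.** `magnitude_spectrum()` defaults to a rectangular window
(Parseval's identity then holds exactly), but the feature path
(`study_features()` and everything built on it) tapers with a Hann window.
The reason is scalloping: the moments of a narrow band containing a strong
spectral line depend on how the line aligns with the FFT bin grid, an
alignment that varies between recordings and subjects. With a rectangular
window this adds enough nuisance variance to measurably degrade held-out
classification; the Hann taper reduces the apparent-magnitude variation
from ~64% to ~15% and suppresses leakage tails.

## The two-stage classifier

Stage one (S1DT) is a decision tree on X1, X4, X6 — Gini impurity, depth
at most 3 — that separates normal from abnormal studies. Its split
thresholds were never published, so the tree is re-learned from data
(`osa_fit()`; rpart, deterministic). The growth controls `minsplit = 10`,
`cp = 0.01` were chosen for leave-one-patient-out stability on simulated
cohorts.

Stage two (S2LR) estimates the AHI of studies the tree calls abnormal:

    AHI = 11.94 + 23.06·X2² + 8.74·X3 − 15.04·X5

These reference coefficients ship frozen as the default predictor
(`s2lr_predict()`, `osa_model()`); refitting is opt-in via `osa_fit()`,
which regresses `ahi ~ X2² + X3 + X5` on studies whose gold-standard AHI
is at least 5 — the regression only ever predicts for studies already
gated abnormal, so normal studies would only dilute it.

Severity follows from the estimate: `< 5` normal, `[5, 15]` mild,
`> 15` moderate-severe (`severity_from_ahi()`). The boundary at 15 is
closed on the mild side. If the tree says abnormal but the regression
returns less than 5, the estimate is clamped to 5.0 (mild): the abnormal
gate asserts AHI ≥ 5, and a lower regression value is inconsistent with
it. Studies gated normal carry the censored token `"<5"` — no numeric
estimate exists for them.

`osa_lopo()` evaluates the pipeline by leave-one-patient-out
cross-validation: all of a subject's studies, every night and every
setting, are held out together, so repeated nights of one person can never
leak between training and test. Folds whose training set loses a class
are reported as fold errors rather than silently skipped.

## Per-night and per-subject AHI protocol

Nights recorded concurrently with a gold standard are scored whole-night
(`whole_night_ahi()`): clinician-invalidated spans are excised (cut out and
concatenated, not zero-filled — the features are distributional over
frequency, and imputation would fabricate spectrum), and the classifier
runs once on the remainder.

Unattended load-cell-only nights have no clinician to mark artifacts, so
they are scored by a windowed protocol (`windowed_ahi()` →
`reject_outliers()` → `night_from_series()`, or `windowed_night_ahi()` in
one call): overlapping 3 h segments (the 2–4 h minimum recommended for
sleep apnea testing motivates the window length) stepped by 1 h, one AHI
estimate per segment, a rolling median filter (span 5 estimates) dropping
segments that deviate from the local median by more than 10 events/h, and
the night's AHI as the mean of the survivors. The step, span and threshold
are engineering defaults, configurable and logged, not published values.
Windows graded normal enter the series at 2.5 events/h (the midpoint of
the normal range); a night whose surviving windows vote normal by majority
is censored `"<5"`. The filter never empties a series: if everything would
be rejected, the value nearest the global median survives.

A subject's final diagnosis is the *highest* estimate across their nights
(`aggregate_subject()`): OSA has high night-to-night variability and
clinical practice errs toward the more severe reading. The final AHI is
censored only if every night is censored. This max rule is also what makes
multi-night screening highly sensitive but less specific — a single
false-abnormal night flips the subject.

## Evaluation suite

`evaluate_tables()` scores the packaged per-night study tables (a 14-subject
pilot cohort: 13 scored in-clinic polysomnography nights, 22 home nights
with concurrent HSAT sensors, 24 home load-cell-only nights, plus a
deployability survey). Conventions that matter for reproducing the printed
statistics:

* Confusion metrics treat `abnormal` as the positive class; the failed
  0.00 h clinic study is excluded from scoring but kept in the tables so
  cohort accounting matches the study flow chart.
* Severity is scored per study-night with both actual and predicted grades
  derived from the AHI values via the severity mapping (censored
  predictions are `normal`; actual moderate and severe collapse into
  moderate-severe).
* Bland–Altman differences are oriented actual − predicted (positive bias
  = underestimation) with limits of agreement bias ± 1.96 × population SD,
  over only the 20 study-nights where both AHIs are numeric. From the
  printed table values this yields −25.53 / 29.66; the upper limit printed
  in the original report (29.69) centers on a bias of 2.08 rather than the
  printed 2.06 and is evidently computed from unrounded predictions that
  were never published, so it cannot be recovered exactly from the tables.
* The paired comparison of HSAT-concurrent versus load-cell-only nights
  (`compare_hsat_effect()`) averages each subject's nightly estimates with
  censored values imputed at 2.5 events/h (configurable) and applies a
  two-sided paired t-test over the 12 subjects present in both tables. The
  imputation and pairing convention of the original analysis is unstated;
  every plausible convention we tried agrees on non-significance but none
  reproduces the printed statistic exactly, so only the qualitative
  conclusion should be compared.
* Reported percentages round half-up to one decimal.

## The synthetic-data generator

No public recordings exist for this kind of device, so `simulate_recording()`
and `simulate_cohort()` generate 4-channel recordings with known ground
truth. A simulated night contains: a raised-cosine breath train (default
0.2415 Hz, 14.5 breaths/min) with inspiratory/expiratory asymmetry so the
breathing line carries strong harmonics; a pulse-like ballistocardiogram
(default 1.19 Hz, 71 bpm, with a second harmonic) at about a tenth of the
respiratory amplitude, amplitude-modulated by respiration; apnea/hypopnea
events placed as a renewal process with exponential gaps (rate-corrected so
the long-run event rate equals the target AHI; events are disjoint by
construction and realized counts stay within Poisson dispersion), each
suppressing respiratory amplitude by a depth drawn from (0.3, 1] — depths
of 0.9 and above are labelled apnea — for 10–60 s; event-phase physiology
(breathing and heart rate slow during the obstruction — the bradycardia
half of the classic brady–tachy pattern); recovery physiology after each
event (deeper and ~1.5× faster breathing, a heart-rate surge with a
stroke-volume surge, holding a plateau before releasing, and usually a
brief arousal movement); slow baseline drift; occasional spontaneous
position-change movements; and white sensor noise distributed over the
four channels by shoulder/hip weights.

**Why the oscillators are metronome-like.** The six features are shape
moments of narrow-band magnitude distributions. For any noise-like or
smeared process, narrow-band FFT magnitudes converge to a Rayleigh
distribution regardless of the underlying physiology, so the moments carry
no information; they only leave the Rayleigh limit when stable spectral
lines occupy a few bins of a band. The generator therefore uses very
stable rates (0.1% slow jitter) placed so that event-switched lines fall
inside the published bands: recovery tachypnea at 1.525 × 0.2415 ≈ 0.37 Hz
(X2), the 4th breathing harmonic at ≈ 0.97 Hz (X3), the cardiac line at
1.19 Hz (X4) surging to ≈ 1.41 Hz (X5), the 7th breathing harmonic at
≈ 1.69 Hz (X6), and the event-gate spectrum itself in 0.06–0.08 Hz (X1).

This is the central realism trade-off to understand when reading test
results: real breathing and heart rates vary far more than 0.1%, and in a
real cohort the discriminative bands are whatever ANOVA selection finds
for that population — the published bands encode the real cohort's
physiology, which no simulator can reproduce. Passing simulated-cohort
tests therefore demonstrates that the pipeline's machinery (preprocessing,
features, two-stage fit, cross-validation, protocol) recovers a known
signal when one is present in the published bands; it does not predict
accuracy on real beds. The generator also omits position changes, sleep
staging and REM structure, inter-subject anatomy, and sensor
non-linearities.

`simulate_cohort()` draws one base AHI per subject — by default from the
pilot cohort's severity mix (6 normal / 5 mild / 3 moderate-severe in 14,
with AHI uniform in 0–4, 5–15 and 15–45 respectively) — applies ±20%
night-to-night jitter, and returns a feature/label table ready for
`osa_fit()` / `osa_lopo()`.

## Problem sizes used by the tests

The test-suite and acceptance cohorts simulate 6 h nights at 20 Hz: the
entire analysis lives below 5 Hz (filter passband) and the features below
2 Hz, so sampling at 20 Hz instead of the device's 250 Hz changes nothing
downstream while keeping a 100-study cohort's simulation around a minute.
Night *duration* is kept at the realistic 6 h because it matters directly:
the number of FFT bins per 0.02 Hz band equals 0.02 × duration-in-seconds,
and the moment estimates need hundreds of bins to stabilize. Smaller unit
tests use shorter signals (150 s–2 h) wherever only mechanics are being
checked.

## Known limitations

* The stage-one tree must be learned from data; with the frozen reference
  model alone, only the regression stage is available.
* Mild-versus-normal discrimination near AHI = 5 is intrinsically hard:
  nights a couple of events apart are physically nearly identical, and
  both the original clinical results (69% in-clinic accuracy) and the
  simulated cohorts show the error mass concentrated at that boundary.
* The windowed protocol's step, median span and rejection threshold are
  defaults without a published reference; sensitivity to them is not
  characterized.
* Censored `"<5"` estimates force conventions (imputation at 2.5 events/h)
  into the paired comparison and any rank statistics that include
  normal-graded studies.
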