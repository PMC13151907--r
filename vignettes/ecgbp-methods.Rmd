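---
title: "Methods: simulating, featurizing and evaluating ECG-based blood pressure estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating, featurizing and evaluating ECG-based blood pressure estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The question and the shape of the pipeline

`ecgbp` implements, as a reusable and tested pipeline, the full procedure for
asking whether blood pressure (BP) can be estimated from 30-second single-lead
ECG recordings collected asynchronously with cuff-BP readings in ambulatory
settings. Proprietary device logs of this kind are not publicly available, so
the package couples the analysis pipeline to a synthetic-cohort generator
whose statistical structure matches what the analysis assumes: variable ECG
and BP counts per subject, seconds-to-hours gaps between modalities,
sex-specific BP distributions, subject-level BP random effects, short-term BP
drift, and an optional *planted* heart-rate-to-BP coupling that serves as a
positive control.

The pipeline stages are `simulate → clean/pair → features → train →
evaluate`, orchestrated by `run_experiment()` under a single root seed. Every
random stream derives from that seed through `derive_seed()` (a documented
polynomial byte hash of a stage/entity tag), which is what makes two runs of
the same configuration byte-identical down to the exported JSON report.

## The synthetic cohort

**Subjects.** Sex-specific BP baselines are drawn from normal distributions
with defaults matching a large ambulatory cohort: male SBP 127.1 (16.0),
female SBP 123.8 (17.0), male DBP 80.2 (10.5), female DBP 78.9 (11.0) mmHg.
The subject baseline is the subject-level random effect: all of a subject's
readings share it, which is exactly the structure that makes record-wise
cross-validation leak. Baseline heart rate is N(72, 10) bpm between subjects
with 3 bpm record-to-record variation. Abnormal-rhythm record probabilities
default to 14.3% (male) and 12.1% (female).

**ECG waveforms.** Each beat is a sum of five Gaussian waves (P, Q, R, S, T)
with configurable amplitude, center offset and width, placed on an RR grid
derived from the record's true HR plus HRV jitter (RR coefficient of
variation 0.04 for sinus rhythm, 0.25 for irregular rhythms — abnormality is
expressed through RR irregularity, not morphology, because only the label
matters downstream). A Gaussian template was chosen over a dynamical model
because every oracle quantity is then analytic: the true R location, each
wave's 10%-prominence onset/offset (center ± 2.146 sigma) and its area
(amplitude x width x sqrt(2 pi)). P and T offsets and widths shrink with
sqrt(RR) so that neighboring beats' waves stay separated at high heart rates,
mimicking physiologic PR/QT shortening. Each subject receives log-normal
multiplicative jitters on wave amplitudes (10%) and widths (5%) — a
morphology fingerprint that makes subjects identifiable to a flexible model,
which is a prerequisite for demonstrating leakage. White noise (default
0.05 mV) is added on top.

**BP series.** A reading at time *t* is
`baseline + drift(t) + beta * (HR(t) − HR_baseline) + noise`. The drift is a
random walk over the requested reading times whose per-step increment SD is
`drift_rate * dt` minutes — calibrated so BP moves about 5 mmHg RMS over the
3.5-minute pairing window, the rationale for that window — saturating at
8 mmHg for long gaps, decaying with a one-day time constant, and reflected at
±3 population SDs. The saturation and reversion keep months-long observation
windows at realistic within-subject variability (a pure reflected walk
would approach a uniform over ±48 mmHg); neither affects the 3.5-minute
increment law, which the tests verify by Monte Carlo. The coupling
coefficient `beta` defaults to 0: the null world in which the ECG carries no
BP information beyond subject identity.

**Defect planting.** By default a small fraction of records carries
`unreadable`/missing labels or sub-30 s durations, a small fraction of BP
rows is invalid (swapped SBP/DBP or out-of-range values), and some subjects
have unrecorded sex — so the cleaning stages always have real work, and the
cleaning ledger's reconciliation is continuously exercised.

What the generator does *not* emulate: realistic 12-lead morphology,
pathology-specific waveforms, baseline wander, electrode artifacts, or any
genuine physiologic ECG-BP coupling. Passing tests therefore demonstrate the
*pipeline's* correctness and its statistical phenomena (central tendency,
leakage, recovery of planted signal), not that real ECGs lack BP information.

## Preprocessing

The band-pass (0.1–100 Hz) is realized as a Butterworth high-pass (order 2)
plus low-pass (order 4) cascade after explicit mean removal, applied
forward-backward with reflect padding. A single band-pass transfer function
spanning 0.1–100 Hz at 300 Hz sampling puts poles numerically on the unit
circle; the cascade is the standard stable realization. Zero-phase
application preserves fiducial timing (tested: R indices move at most one
sample). The mains notch is the standard two-pole/two-zero design with
Q = 40 at 50 or 60 Hz (config), also forward-backward. Records shorter than
30 s are rejected with reason `too_short`; longer records keep their first
30 s.

## Pairing and cleaning

The cleaning order is: subject age/sex filter (adults 18–90, inclusive
bounds), record-length standardization, rhythm-label filter (six valid
labels; `unreadable` and missing are removed), BP validity (DBP < SBP
strictly; DBP in 20–200, SBP in 30–300 mmHg, inclusive), windowed pairing,
and per-subject capping. Pairing anchors a ±210 s window at the ECG start
(the anchor is a package choice; start, midpoint and end differ by at most
30 s against a 210 s window), averages all in-window validated readings
arithmetically, and records the mean absolute offset as the pair's time gap
— later a model feature. A reading at exactly 210 s is inside; all bounds in
the package are inclusive so boundary behavior is crisp. One reading may
serve several ECGs with overlapping windows. Capping selects at most six
pairs per subject uniformly without replacement, once per experiment seed
rather than per fold, so every learner sees identical folds. Each excluded
item carries exactly one reason code and per-stage counts reconcile exactly
(`n_in − n_out = sum of reasons`), which the tests assert.

## The 128-feature extractor

R peaks are detected from the 10–30 Hz band energy (squared, smoothed
120 ms), thresholded at 0.3 x a running 98th percentile, refined to the
waveform extremum under a 250 ms refractory period. The detector's contract
is ground-truth recovery — exact on noiseless synthetic records, ≥ 0.95
sensitivity/PPV at 10 dB SNR — not any particular published algorithm.

Fiducial points use conventional search windows relative to R (P in
[−300, −80] ms, Q in [−80, −10], S in [10, 80], T in [120, 450], clipped to
the local RR), an isoelectric baseline estimated from the PR segment
(median over [−95, −60] ms before R; a beat-segment median is biased at high
heart rates where waves fill most of the RR interval), Q/S extrema signed
opposite to the R deflection (so inverted QRS resolves consistently), and
onsets/offsets at the 10%-of-prominence crossings. Waves below 7.5% of the R
prominence are flagged absent — flagged, never raised, and never
zero-imputed; the tree learners downstream accept missing values.

Feature groups: per-beat SNR against robust templates (robust weighted
average, with weights inversely proportional to squared distance from the
running average, and pointwise-median beat; SNR capped at +100 dB on clean
data), HR/HRV scalars (mean/median/5th/95th percentile HR, SDNN, RMSSD),
fiducial intervals (QRS, QT, PR, ST, segment levels, peak-pair intervals,
Bazett and Fridericia QTc), amplitudes/areas/ratios, amplitude-to-time
slopes, signal mobility and complexity (computed literally as variance
ratios without the square root — the classic Hjorth definitions take roots,
but the variance-ratio form is the one this pipeline standardizes on), and
the singular-value spectrum of the R-centered beat stack (window = median RR
rounded up to odd), normalized by the largest singular value and zero-padded
to length 45.

No published enumeration of the 128 features exists, so the package's
versioned manifest (`feature_manifest()`, shipped as
`inst/extdata/feature_manifest_v1.json`) is the normative artifact. The
per-beat operations yield 33 quantities; giving all of them mean/median/SD
summaries would overshoot, so the manifest assigns all three summaries to the
21 core measurements and the mean only to 12 derived ones (per-wave areas
except T, the four R-to-wave amplitude ratios, the four slopes):
21 x 3 + 12 + 6 HRV + 2 Hjorth + 45 SVD = 128. The mean ECG-BP time gap and
the subject age join as two supplementary inputs (130 total), and a plugin
slot accepts an external 150-feature extractor (records in, named floats
out; wrong length is a hard error) for a 280-length vector.

## Models

Four sex-by-rhythm strata (male/female x all/sinus-only) are modeled
separately for SBP and DBP regression and for binary BP-class
classification. The learner registry ships `random_forest` and `extra_trees`
(via ranger) and `xgboost` (gradient boosting), is user-extensible, and all
learners run on identical fold data. The ranger wrappers impute missing
features with training-fold medians (ranger has no native NA path); xgboost
consumes NAs natively. Hyperparameters are frozen library defaults, except
xgboost which is deliberately conservative (100 rounds, depth 3, eta 0.05,
`min_child_weight` 20, L2 10): BP-style tabular data has weak signal and
subject-level noise, and an unregularized booster memorizes noise — which
would contaminate the null-calibration property rather than reveal anything.
Classification scores are raw ensemble probabilities; the metrics used are
rank-based or anchored, so recalibration would not change them.

Fixed central-tendency baselines predict the training fold's mean, median or
mode (mode on 1 mmHg bins, ties to the smallest value) for every test
record; they are the yardstick for the central-tendency diagnosis.

## Evaluation

Cross-validation plans are subject-wise (whole subjects per fold — the
leakage-safe design) or record-wise (the leakage-prone contrast), balanced
within one unit, deterministic per seed; predictions from all folds are
pooled before metrics. Regression metrics are ME, SD of error, MAE, SD of
absolute error and Pearson rho; rho is reported as *undefined* for constant
predictions rather than 0, because a constant predictor is exactly the
central-tendency case and must not fake a correlation. The AAMI check is
|ME| ≤ 5 and SD ≤ 8 mmHg (inclusive; the standard bounds the magnitude).
BHS grades come from cumulative |error| percentages within 5/10/15 mmHg
against the A/B/C rows (60/85/95, 50/75/90, 40/65/85). BP categories follow
the AHA table evaluated highest-stage-first, since the raw table is not
mutually exclusive (SBP 125 with DBP 85 satisfies both the Elevated SBP
clause and the Stage-1 DBP clause); an exhaustive truth-table oracle checks
the boundary grid. Binary grouping is Normal+Elevated vs Stage 1+2.
Classification reports AUROC (rank form, verified against pair enumeration
over every 6-record label arrangement) and AUPR, with point metrics at the
smallest-sensitivity-≥ 0.7 operating point, ties broken toward higher
specificity — finite test sets rarely hit 0.7 exactly, so "closest from
above" is the only monotone choice. The central-tendency comparison flags a
run when model MAE ≥ 0.95 x the median baseline's MAE. The bootstrap CI for
rho resamples subjects (clusters), 1000 times, percentile method, seeded.

## Benchmark experiments and problem sizes

Four standing experiments validate the pipeline's science end to end
(`detector_benchmark()`, `null_coupling_benchmark()`, `leakage_benchmark()`,
`coupling_recovery_benchmark()`), at sizes chosen to make each effect's
expected magnitude large against its sampling noise while keeping a full run
in minutes on one core:

- **Detector:** 100 records, clean and at 10 dB SNR.
- **Null coupling:** 500 subjects, 5 records each, one BP per ECG. Expected:
  |rho| ≤ 0.1 with a bootstrap CI covering 0, and model MAE within 5% of the
  median baseline.
- **Leakage:** 300 subjects, 4 records each, subject intercept SD 15 mmHg,
  cuff noise 5 mmHg, no drift, zero coupling. Expected: record-wise minus
  subject-wise rho ≥ 0.2. The inflation exists because HR and morphology
  fingerprint subjects, and record-wise splitting lets the forest recall a
  training subject's BP.
- **Planted coupling (positive control):** beta = 0.4 mmHg/bpm with 5 mmHg
  noise. For the planted signal to be the dominant *predictable* component,
  the recovery cohort collapses the between-subject SBP baseline SD to 0 and
  moves the HR spread (15 bpm) into the record level: with a 16 mmHg
  unlearnable baseline spread no subject-wise model could reach rho 0.6
  regardless of how faithfully the coupling is recovered. Expected:
  subject-wise rho ≥ 0.6 and no central-tendency flag.
- **Determinism:** the 200-subject demo configuration run twice must export
  byte-identical reports.

`scripts/acceptance.R` reruns all of these from scratch under a caller seed.

## Numerical choices and degenerate inputs

Filter edge transients are handled by reflect padding (3 s); the DC test
excludes the first/last two seconds. The RWA iteration runs at most 10
rounds to relative change < 1e-6 and falls back to the plain mean with a
flag. SNR caps at +100 dB when residual power < 1e-12 of beat power;
zero-power beats are missing. Ratio features guard denominators at 1e-6 and
go missing, never infinite. Zero-variance targets train warned constant
models; single-class test sets and sub-minimum training folds are errors
naming the stratum/fold. Ground-truth recovery tests exclude each record's
first and last beats, whose search windows hit the record boundary.

## Known limitations

The Gaussian template cannot express ST elevation, biphasic T waves, or
realistic QRS micro-structure, so fiducial windows tuned here may need
adjustment on real data. Abnormal rhythms alter only RR structure. The
record-wise leakage magnitude depends on how strongly the morphology
fingerprint separates subjects — real cohorts may leak more (richer
morphology) or less (more within-subject drift). The 128-feature manifest is
a faithful reconstruction by group, not a published enumeration; its exact
composition is versioned so downstream results are comparable.
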