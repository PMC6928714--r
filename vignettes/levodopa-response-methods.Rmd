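---
title: "Estimating the levodopa response from wrist-sensor recordings: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating the levodopa response from wrist-sensor recordings: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

The levodopa challenge test (LDCT) quantifies how much a person with
Parkinson's disease (PwP) improves on levodopa: the motor section of the
Unified Parkinson's Disease Rating Scale (UPDRS III) is scored before a
morning dose ("OFF") and again at peak effect ("ON"), and the response is
summarized as the absolute improvement (abs∆ = OFF − ON) or the percent
improvement (%∆ = abs∆ / OFF × 100). The test is informative — it supports
the diagnosis and gates advanced therapies such as deep brain stimulation —
but it is burdensome: it requires a hospital visit in the unmedicated state.

A wrist-worn logger that scores bradykinesia (BKS) and tremor amplitude
every two minutes over about six days observes the response to the *first
morning dose* on every recorded day. `wristldct` implements a pipeline that
turns such epoch streams into an instrumented LDCT: engineered features
around the first daily dose, an ordinal severity model trained against
clinical UPDRS III labels, per-subject response estimates, and the
exclusion heuristics that sharpen the clinically meaningful signal.
Because the clinical recordings this class of method is developed on are
proprietary, the package ships a synthetic cohort generator with known
ground truth; every stage is tested against it.

## Epoch model and activity labeling

An epoch is a 2-minute interval on a grid aligned to midnight; timestamps
are minutes since recording start with calendar days at multiples of
1440. Epochs carry a BKS value, a tremor amplitude (0 = no tremor) and an
off-wrist flag. Off-wrist epochs are unavailable for analysis: they are
dropped from every window (windows shrink; nothing is imputed).

Sustained high BKS indicates sleep or inactivity rather than observed
bradykinesia, so epochs whose *linearly weighted moving median* of BKS
over a 15-epoch (30 min) window exceeds 40 BKS units are labeled
`inactive` and excluded from all downstream statistics. All remaining
epochs are `active`. (A literal reading of the source glossary would call
epochs "active" when that moving median is ≤ 0, which would exclude
nearly everything; we treat this as an erratum and define active as
not-inactive and not-off-wrist.)

## Features

All features are computed over a centered 15-epoch window of active,
on-wrist epochs:

* **Moving percentiles of BKS** (10th, 25th, 50th, 75th, 90th), using the
  nearest-rank (inverted-CDF) convention.
* **Weighted moving percentiles of BKS** with a triangular kernel: the
  weight is maximal at the window center and declines linearly and
  symmetrically on each side. We use weights $(h + 1 - |j|)/(h + 1)$ for
  offsets $j = -h, \dots, h$, which reach zero just *outside* the window
  so every in-window epoch keeps positive weight. The weighted q-th
  percentile is the smallest value whose cumulative normalized weight
  reaches $q/100$; substituting uniform weights reproduces the unweighted
  statistic exactly (a tested identity).
* **Tremor features**: the moving and weighted moving median of tremor
  amplitude, and the log transform $\log_{10}(1 + \mathrm{TA\_WM50P})$,
  which brings tremor onto a scaling comparable with BKS and maps "no
  tremor" to 0.

Windows shrink at series edges and around excluded epochs; an epoch with
no usable neighbour yields a missing feature. The model consumes
`BKS_M10P`, `BKS_M25P` and `TA_WM50P_Log`; the remaining candidates are
retained for the relevance/redundancy analysis below.

## Dose and effect windows

The **dose time (DT)** of a day is the 5 epochs (10 min) centered on the
epoch containing the acknowledgement of the first dose reminder, minus
inactive and off-wrist epochs. The **effect time (ET)** is found once per
recording: each day is aligned on its acknowledgement, the across-day
median of usable BKS is taken at every 2-minute offset and smoothed with
a 5-point centered moving average (the source method's smoothing operator
is unspecified; median-then-average is robust to a single corrupted day
and is our documented choice), and the ET is the offset of the *minimum*
of this smoothed weekly series within the closed 46–90 min search window,
earliest offset on ties. The source text says "peak"; since BKS falls as
the drug acts, peak effect is the trough of BKS. The per-day ET window is
the 5 epochs centered at that fixed offset. Pooling the per-day windows
gives up to 30 epochs per week, summarized by their mean and sample
(n − 1) standard deviation.

Controls carry no dose events; they are processed at a nominal dose time
(07:00 when building the model, chosen so sleep/inactivity levels resemble
the patients' first-dose context; 10:00 when estimating the response, to
avoid sleep) with the ET taken at their weekly-series trough.

## Feature relevance and redundancy

Relevance of each continuous feature to the 6 severity classes is scored
by mutual information with a k-nearest-neighbour estimator for mixed
continuous/discrete data (k = 6): for each sample, the distance to its
k-th neighbour *within its own class* defines a radius, and the count of
samples of any class inside that radius enters a digamma average. Joint
(2-dimensional) MI uses max-norm distances, which keeps it consistent with
the marginal estimator. Percentile features are heavily tied, which breaks
k-NN estimators, so a tiny seeded jitter (10⁻¹⁰ of the value range) is
added before distances are computed. Estimates are reported in nats and
clipped at zero.

Redundancy-aware ranking uses joint mutual information maximization
(JMIM): pick the feature with maximal marginal MI, then iteratively add
the candidate whose *minimum* joint MI with any already selected feature
is maximal. Ties are broken by input order.

## The ordinal severity model

UPDRS III totals are first harmonized: totals on the older scale gain 7
points (the MDS revision added items), MDS totals pass unchanged. The
adjusted score is binned into 6 **motor function severity levels
(MFSL)**: level 0 below 10, then 12.5-point increments, with everything
at or above 60 in level 5. Scores exactly on a boundary belong to the
level above. The 6-class problem is decomposed into 5 binary problems:
classifier $k$ separates scores below versus at-or-above threshold $k$
(10, 22.5, 35, 47.5, 60).

Training samples are window epochs: DT epochs labeled with the subject's
OFF severity level, ET epochs with the ON level, control epochs with
level 0. For each classifier, 30% of the samples of each binary class go
to a held-out test set with *subject grouping* — a subject's epochs never
straddle the split (epochs of one subject are strongly dependent).
Features are standardized with training-set statistics only. The default
classifier is an L2-regularized logistic regression whose penalty is
tuned by 10-fold cross-validation (folds also grouped by subject);
`pca_logistic` replaces the two collinear BKS percentiles by their first
principal component, and RBF-kernel SVC and gradient-boosted trees are
available as optional nonlinear families. Per-epoch prediction is the
plain sum of the 5 hard votes at probability 0.5, an integer 0–5;
non-monotone vote patterns are resolved by the sum without any
monotonicity repair (a probability mode exists but is off by default).

## The instrumented challenge and its exclusion flags

For each subject, the per-epoch severity predictions over the pooled DT
epochs are averaged into `MFSL_DT`, likewise `MFSL_ET`, and the response
is `abs∆ = MFSL_DT − MFSL_ET` with `%∆ = abs∆ / MFSL_DT × 100` (missing
when `MFSL_DT` is 0 rather than infinite). Subjects whose DT or ET window
is empty receive a reason code instead of a response.

Three heuristics flag subjects whose comparison with the clinical test is
unreliable; all three apply to patients only (controls are retained
everywhere):

* **Uncertain zone.** Clinical responses with 11 ≤ abs∆(UPDRS) ≤ 14 (a
  4-point band centered on one severity increment) are neither clearly
  meaningful (> 14) nor clearly insignificant (≤ 10).
* **Already ON.** If `MFSL_DT` is in the treated range (< 3) while the
  model's severity estimate from 46 min after the first dose until 18:00
  (pooled per-epoch mean plus one standard deviation) exceeds
  `MFSL_DT + 1`, the morning severity likely understates the subject's
  worst state (medication before the first reminder, or sleep benefit).
* **Excess variability.** Amplitude: the per-epoch severity SD exceeds 1
  level in *both* the DT and ET pools. Latency: the per-day trough
  latencies (within-day argmin of the day's dose-aligned smoothed BKS in
  the search window, 9-point smoothing) have SD above 11 min — a quarter
  of the search window. The source describes the latency criterion
  ambiguously (its two passages conflate amplitude and latency); this
  operationalization is our documented choice, and the combined
  "variable" exclusion is amplitude-flag OR latency-flag.

## Evaluation

The instrumented response is scored against the binary clinical response
(class 1: abs∆(UPDRS) > 10; controls are class 0 and augment the
insignificant class) by ROC AUC — computed as the rank statistic, which
equals pairwise concordance with ties at ½ — and by a class-averaged PR
AUC: the mean of the two one-vs-rest step-wise average precisions (the
negative class scored by negated scores). Scenario tables recompute both
AUCs after cumulative exclusions (all; already-ON; uncertain; both; plus
variability), with support counts split by class and by patients versus
controls. In the "all" scenario, uncertain-zone subjects are retained as
class 1 (their improvement exceeds the insignificance bound); they are
removed only in uncertain-excluding scenarios.

## The synthetic cohort generator

The generator emulates the study conditions end to end; its defaults are
the conditions, not tuning knobs:

* 6-day recordings at 2-minute epochs; sleep 23:00–06:30 with BKS around
  55 (SD 4), well above the inactivity threshold; daytime inactivity as
  bout-like Markov excursions (stationary occupancy 8%, mean bout 15
  epochs — sleep and rest are bouts, not i.i.d. epochs, and initializing
  from the stationary law makes the expected flagged fraction equal the
  configured rate exactly); off-wrist bouts at 2%.
* An affine severity link BKS = 2 + 0.45 × UPDRS III plus Gaussian epoch
  noise (SD 6 BKS): the device's bradykinesia score is linearly related
  to clinical severity. OFF severities are drawn by cycling the five
  patient severity levels (referral cohorts are enriched for
  moderate-to-severe disease, and the cycle guarantees every ordinal
  classifier support on both sides even in small cohorts) with the OFF→ON
  improvement truncated normal around 22 ± 11 points.
* One first-of-day reminder at 07:00 (wake 06:30), acknowledged 0–4 min
  later. The effect declines from 10 min after acknowledgement to a
  trough at a per-day latency drawn from a truncated normal on [46, 90]
  min (mean 62, pooled SD 10; the day-to-day spread differs between
  subjects to emulate stable versus erratic gastric emptying) and wears
  off over 120 min. Day-to-day amplitude varies with CV 0.15.
* 19% of patients are "already ON": their morning severity sits at the
  ON level until midday and deteriorates to the OFF level by 14:00.
  Eligibility requires an ON level below 30 with at least 16 points of
  OFF–ON contrast, since an undetectably small contrast could not be
  flagged by any method.
* Tremor is present per awake epoch with probability increasing in
  current severity and log-normal amplitude; controls have zero severity,
  low flat BKS and no dose events.

What the generator does *not* emulate: raw 50 Hz accelerometry and the
device's scoring algorithm (BKS is produced directly), dyskinesia,
pharmacokinetic compartment dynamics, circadian severity drift, and
medication schedules beyond the first daily dose. Passing tests therefore
demonstrate that the pipeline recovers known ground truth under the
stated generative assumptions — not device-level validity on real
recordings.

## Numerical choices and degenerate inputs

* Percentiles: nearest-rank unweighted; cumulative-normalized-weight
  threshold weighted — chosen so the uniform-kernel equivalence is exact.
* Empty windows yield missing values; subjects with empty DT/ET pools get
  reason codes, not errors; %∆ at zero denominator is missing.
* Ties in the ET search resolve to the earliest offset; MI ties are
  broken by seeded jitter; JMIM ties by input order.
* Sample SD uses the n − 1 denominator throughout; single-day recordings
  leave latency variability undefined.
* All randomness is seeded; a pipeline run fans a single seed out to
  per-stage child seeds (`seed × 1000 + stage`), and identical seeds give
  byte-identical outputs.

## Problem sizes used in the tests

The test suite exercises module behaviour on small constructed series and
cohorts of 20–40 subjects, and runs the full recovery analysis on one
simulated cohort of 150 patients and 150 controls over 6 days (about 1.3
million epochs) under the default generator conditions. On that cohort the
suite requires held-out ROC AUC ≥ 0.85 for every threshold classifier,
monotone mean predicted severity across true severity strata, already-ON
detection sensitivity and specificity ≥ 0.8, and non-decreasing scenario
AUCs along the cumulative exclusion chain. The estimator checks use up to
5000 samples against an analytic two-class Gaussian location model
(|estimate − truth|/truth < 15%).

## Known limitations

* The latency-variability flag inherits the noise of locating a trough on
  a single day's smoothed series; at realistic epoch noise it fires more
  often than the amplitude flag. The threshold (11 min) and smoothing
  bandwidth are configurable.
* The severity model is a bank of independent binary classifiers, not an
  ordinal regression with proportional-odds constraints; vote patterns
  need not be monotone and are resolved by summation.
* MI values depend on the estimator variant and sample; they are
  reported in nats and are not comparable across datasets.
* Boundary severity scores (exactly 10, 22.5, ...) are assigned to the
  upper level; the source does not state its convention.
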