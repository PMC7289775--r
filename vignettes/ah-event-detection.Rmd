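---
title: "Cascaded detection of apnea-hypopnea events: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cascaded detection of apnea-hypopnea events: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(AHcascade)
```

## The problem

Sleep apnea-hypopnea syndrome is graded by the apnea-hypopnea index (AHI):
the number of respiratory events per hour of sleep, with the conventional
severity cutoffs 5, 15 and 30 events/h. An apnea is a near-total cessation
of airflow (a more than 90% amplitude drop) lasting at least 10 s; a
hypopnea is a partial reduction (more than 30%) of the same minimum
duration accompanied by at least a 3% drop in arterial oxygen saturation.
Full polysomnography scores these events from many channels; this package
implements a reduced montage: a nasal-flow (NF) thermistor channel and a
pulse-oximeter SpO2 channel, both on a common 8-Hz grid, feeding a cascaded
random-forest classifier whose per-second output is turned into discrete
events and an AHI estimate. Apneas and hypopneas are pooled into a single
positive class ("AH"); sub-typing, central/obstructive discrimination and
sleep staging are out of scope.

## Preprocessing

Four steps, in order:

1. **Artifact masking** (`removeArtifacts()`). SpO2 below 50% is
   physiologically implausible and treated as oximeter dropout. Samples are
   *masked*, not deleted, so the two channels stay aligned on one time
   axis; segments whose window is more than 10% invalid are excluded from
   training and evaluation rather than imputed.
2. **Flow filtering** (`filterNF()`). A 4-point sliding average (causal by
   default, switchable to centred) suppresses high-frequency artifact
   noise, then a third-order Butterworth high-pass at 0.05 Hz removes
   baseline drift. The high-pass runs forward-backward so that event
   timing is not delayed. Because direct-form IIR filtering has an edge
   transient of roughly `1/cutoff` seconds, the zero-phase pass operates on
   an odd-reflection-padded copy of the signal (pad length `3/cutoff`
   seconds) and the padding is discarded afterwards; both ends of the
   record are then transient-free, which matters because segments are
   extracted all the way to the edges.
3. **Segmentation** (`segmentize()`, `labelSegments()`). Sliding windows
   of 60 s and 10 s, both stepped by 1 s; a segment is labelled AH when its
   overlap with the *union* of annotated events strictly exceeds 5 s.
   Union semantics make the label invariant to how an event happens to be
   split across annotation rows; the strict inequality means an overlap of
   exactly 5 s is labelled N.
4. **SpO2 alignment** (`alignSpO2()`). Desaturation trails the airflow
   signature by roughly the lung-to-finger circulation time, so SpO2 is
   advanced by `tau_s = 23` s (any value in (0, 30) is accepted; 23 is the
   operating point this design is built around). The trailing 23 s, for
   which no future SpO2 exists, are marked invalid. A sweep harness is not
   re-run by default; `tau_s` is an ordinary configuration field.

## The 19 features

Per segment, after preprocessing (`extractFeatures()`):

* **Breaths.** Local extrema of the filtered flow are paired into breaths;
  the tidal volume `Ft` of a breath is the difference between its two
  extreme values. Extrema are accepted when the swing exceeds 5% of the
  whole-record signal range (`prominence_frac`, configurable); the
  detector is a threshold-crossing peak/valley scan, so emitted extrema
  always alternate. The 5% default is small enough to keep residual
  breathing during apneas visible (those breaths are exactly the ones the
  drop-count features need) and large enough to ignore sensor noise.
* **Baselines.** `Fb` is the maximum `Ft` over the 30 s preceding the
  segment; `Spbm`/`Spba` are the maximum/mean valid SpO2 over the same
  window. At recording start, or when the lookback is empty, the
  within-segment values are the documented fallback.
* **Flow features.** Mean/SD/range of `Ft`; counts and fractions of
  breaths dropping more than 30% (`Fha`, `Fhap`) and more than 70%
  (`Fap`, `Fapp`) below `Fb`; breaths staying above 85% of `Fb`
  (`Fnor`, `Fnorp`); and `Fkur`, the fourth standardized moment of the
  magnitude-spectrum values in 0.2-0.4 Hz. Breathless segments emit an
  all-zero flow sub-vector rather than missing values, so the classifier
  never sees missingness.
* **SpO2 features.** SD, range and last-minus-first value; seconds below
  92% and 91%; seconds below 98% of `Spbm` and of `Spba`; and the
  desaturation levels `Spldm = Spbm - mean(SpO2)` and
  `Splda = Spba - mean(SpO2)`. Durations are reported in seconds (sample
  count divided by the rate); only valid samples contribute.

Two readings of the spectral-moment feature are defensible — a moment of
spectral magnitudes or a band-limited time-domain kurtosis. The package
computes the standardized fourth moment of the magnitude-spectrum bins in
the band, which is scale-invariant by construction and peaks when breathing
energy is concentrated at a single frequency. On 10-s windows the 8-Hz
grid only yields three spectral bins in the band, so the feature is weak
there and carries most of its information on 60-s windows; it is retained
for both for uniformity of the feature set.

## The cascaded classifier

A 10-tree random forest over 60-s segments screens the night using only
six features (`Fha`, `Fhap`, `Spstd`, `Spran`, `Spdum`, `Spdua`): cheap,
high-sensitivity coarse detection. A 20-tree forest over 10-s segments,
using all 19 features, classifies only the start seconds screened in. The
default gating rule is *containment* — a 10-s window is forwarded only if
some AH-predicted 60-s window fully contains it — with an any-overlap
alternative available. Containment is the strictest reading and gives the
cascade its defining property: the set of AH start seconds after gating is
always a subset of what the 10-s forest alone would produce.

Class weights are the inverse ratio of the class counts, compensating the
heavy N majority. Both forests are trained on reference labels directly
(the 10-s stage is not trained on the screen's output). Tree counts are
10 and 20; remaining hyperparameters are the forest library's defaults and
are recorded in the model object.

Both stages are *probability* forests thresholded at 0.5 rather than
majority-vote classifiers: with an even tree count, vote ties would
otherwise be broken randomly at prediction time, making predictions depend
on which other rows share the prediction call and breaking both exact
reproducibility and the subset property above. The 0.5 threshold with a
deterministic tie-to-N rule restores both.

Evaluation uses twofold cross-validation (`crossvalidate()`): each half of
the pooled segments trains the model that predicts the other half, so
every segment is predicted exactly once while unseen in training. The
default split is segment-level, which mirrors how such cascades are
usually benchmarked but lets overlapping windows of one event fall on both
sides of the split; the subject-level mode avoids this leakage and is the
honest choice when generalization across patients is the question.

## From labels to events

The per-second 10-s predictions are corrected by two run-length rules
(`correctSequence()`), then maximal AH runs become events
(`eventsFromSequence()`):

1. A genuine event of at least 10 s must produce at least 10 consecutive
   AH-labelled start seconds, so shorter AH runs are reset to N.
2. Two valid events must be separated by more than 5 N start seconds;
   shorter gaps between surviving runs are reset to AH, merging them
   (a gap of exactly 5 merges). Merged runs are not re-tested against
   rule 1.

Both boundaries are configurable. The correction is idempotent, and a run
over starts `[a, b]` becomes the event `[a, b + 10)` — the union of the
covered windows. AHI is the event count divided by the analysed recording
duration in hours; since no sleep staging is performed, total recording
time stands in for sleep time. Severity follows the 5/15/30 cutoffs with
half-open intervals (an AHI of exactly 5 is MILD).

## Evaluation metrics

`segmentMetrics()` gives accuracy, sensitivity and specificity of the 2x2
segment confusion (AH positive), half-up rounded to one decimal — base R's
round-half-even would disagree with conventionally printed tables.
`severityReport()` binarizes the 4x4 severity matrix at each cutoff,
reports SEN/SPE/PPV/ACC, their cross-cutoff means, and unweighted Cohen's
kappa. The means are taken over the *rounded* per-cutoff values, matching
the convention of printed clinical tables (with full-precision averaging
the PPV mean would differ in the last digit). `ahiAgreement()` reports
Pearson correlation and Bland-Altman mean difference with 1.96-SD limits
of agreement.

## The synthetic generator

`generateRecording()` exists so the whole pipeline can be trained and
tested with no external data. It emulates the structure the detector
assumes, with defaults fixed once as the package's standing study
conditions:

* breathing as a frequency- and amplitude-modulated 0.25-Hz sinusoid
  (one breath per 3-5 s), with 0.005-Hz baseline drift (deliberately below
  the 0.05-Hz high-pass cutoff, so the filter is exercised) and white
  noise;
* events scheduled by a renewal process (exponential gaps plus a 15-s
  minimum separation) targeting a configurable AHI; durations uniform on
  12-28 s — clinically scored events average roughly 18-19 s, and the 12-s
  minimum guarantees that a single event survives the strict 5-s labelling
  rule and the 10-run validity rule on its own;
* apneas scale the flow envelope to below 10% of baseline (default
  residual up to 5%), hypopneas to 30-60%, with 1-s raised-cosine edges;
* each event triggers a 3-10% desaturation starting 23 s after event
  onset (half-cosine fall over 10 s, exponential recovery), and SpO2 is
  quantized to integer percent like a pulse oximeter;
* oximeter dropouts (values of 20-45%) are injected in 1-3 s bursts
  covering 2% of samples by default — dataset-wide dropout fractions as
  high as ~6% occur in clinical archives, and tests that need a specific
  rate set it explicitly.

`generateCohort()` draws per-subject target AHIs from severity-specific
ranges — U(1, 4.5), U(6, 14), U(16, 29), U(31, 55) — centred near typical
group means, with per-subject seeds derived deterministically from one
master seed. The reference cohort structure is 2/12/5/5 subjects across
the four severity classes.

What the generator does *not* emulate: arousal-terminated hypopneas
without desaturation, periodic (Cheyne-Stokes-like) breathing, positional
and REM-dependent clustering of events, oximeter averaging-window
dynamics, and genuine inter-subject variability in breath morphology.
Passing tests on synthetic cohorts therefore demonstrates that the
pipeline is implemented correctly and recovers known structure — not that
clinical-grade accuracy carries over to real recordings; the synthetic
signals are considerably easier to classify than clinical ones.

## Numerical choices and degenerate inputs

* Half-open time intervals `[onset, onset + duration)`, 0-based seconds.
* Strict boundaries: `> 5 s` overlap for AH labels; `>= 10` run validity;
  gap `<= 5` merges; all configurable.
* Zero-breath / all-invalid segments produce documented all-zero feature
  vectors; unusable segments (over 10% invalid samples) are dropped from
  feature tables and reported as UNKNOWN in label sequences, which the
  event detector treats as N.
* All randomness flows from explicit seeds (generator, fold split,
  forests); forests run single-threaded at training and prediction so
  results are bit-reproducible.
* Recordings at other native rates are converted on read: sample-and-hold
  upsampling for slower channels (typical 1-Hz oximetry), mean decimation
  for faster ones; only integer rate ratios are accepted.

## Problem sizes used in the shipped checks

The package's own test and acceptance runs use 24 one-hour synthetic
recordings in the 2/12/5/5 severity mix (~86,000 10-s and ~85,000 60-s
segments cohort-wide), twofold segment-level cross-validation, and 10,000
random label sequences for the run-length oracle. One-hour nights keep a
full cohort evaluation in the minutes range while leaving every rate
parameter (events/h, desaturations, dropout) at its nightly value.

## Known limitations

* The pooled AH class cannot be separated back into apneas and hypopneas,
  nor central from obstructive events.
* Hypopneas whose flow reduction hovers near the 30% boundary with shallow
  desaturation are intrinsically hard for the feature set; the 60-s screen
  can also veto isolated events its coarse features miss.
* AHI uses total recording time, not sleep time, so it underestimates the
  clinical index in proportion to wake time.
* Segment-level cross-validation shares overlapping windows between folds;
  use `split = "subject"` for leakage-free estimates.
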