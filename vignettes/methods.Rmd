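---
title: "Methods: from facial meshes to a subject-independent pain classifier"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from facial meshes to a subject-independent pain classifier}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meshpain)
```

`meshpain` turns depth-camera facial mesh streams of deeply sedated
ICU patients into a binary pain-presence classifier evaluated under a
strict subject-independent protocol. This vignette is the package's
account of the science: the model and its assumptions, the parameters
that matter, the numerical choices, what the synthetic generator does
and does not emulate, and the known limitations.

## The data model

A mesh frame is an ordered set of exactly 1,220 3D points (meters) in
a head-centred frame: the origin sits behind the face, and the
tracker's registration makes point positions invariant to head pose
and distance, so point motion encodes facial expression only. Frames
arrive at a variable rate — nominally 20 Hz, ranging roughly 15–45 Hz
— with dropouts whenever the face cannot be detected, and with a short
(< 0.5 s) stretch of unreliable "readjustment" meshes each time the
tracker reacquires the face. The package assumes the mesh is already
registered: face detection and registration are out of scope.

BPS annotations live on the same clock: each record carries the facial
expression sub-score (1–4) and the total BPS (3–12). Only the facial
sub-score is used for labelling; predicting total BPS or pain
*intensity* is explicitly out of scope, because diversity across pain
levels in this population is too poor to support it — the task is
presence vs absence.

## AU features: strategies s1 and s2

Each of the six features reduces a frame to one number via a
hand-chosen point subset \(P\):

\[
\mathrm{s1}(P) = \frac{1}{n}\sum_{p \in P}\lVert p - p_\text{nose}\rVert_2,
\qquad
\mathrm{s2}(P) = \frac{1}{n}\sum_{p \in P}\lVert p - \bar p\rVert_2,
\quad \bar p = \frac{1}{n}\sum_{p\in P} p .
\]

s1 measures motion toward a nose-bridge anchor vertex that is not
expected to move (brow lowering, lip raising pull their regions toward
it); s2 measures contraction of a region onto itself. AU4 gets both
views because brow lowering combines movement toward the nose with
brow-to-brow contraction; AU7 applies s2 to each eyelid separately and
averages, so one eyelid's contraction is not diluted by the distance
between the two eyelids. Both operators are built from pairwise
distances, hence exactly invariant to rigid motion and homogeneous of
degree one under scaling — properties the test suite asserts.

The features carry no activation calibration: they correlate with AU
activation within a subject but are offset by morphology between
subjects. Between-subject differences are left to the model stage
(per-fold z-scoring); no per-subject normalisation happens here.

The anchor is a mesh *vertex*, not a fitted point: fitting would make
it depend on the very motion it is meant to be invariant to. Because
the device's hand-chosen subsets are not public, the default map is
defined on the synthetic template's named regions and shipped as a
JSON config so real index sets can be substituted. Point indices are
1-based throughout, following R convention, both in the API and in the
JSON config format.

## Preprocessing

Three rules, applied in this order per feature series:

1. **Gap split + readjustment removal** (`gap_threshold_s = 0.1`,
   `readjust_s = 1.0`): any inter-sample interval strictly greater
   than 0.1 s is a gap; the first 1.0 s of every uninterrupted run is
   removed. The readjustment itself lasts under half a second; a full
   second is a conservative margin. The boundary case (interval
   exactly 0.1 s) is pinned as *not* a gap, for determinism. The
   session's first run is trimmed too: the tracker performs the same
   readjustment on initial detection, so symmetry is both physically
   right and simpler.
2. **Short-run pruning** (`min_segment_s = 20`): runs with
   `t_last − t_first < 20 s` are dropped — short runs indicate the
   face was hard to detect, so their values are unsafe. Duration is
   measured on timestamps, not sample counts, because the rate varies.
3. **Smoothing** (`smooth_window_samples = 20`): a 20-*sample* centred
   moving average (about one second at the nominal rate), truncated at
   run edges, applied after the structural rules so the average never
   bridges a gap. The sample-count reading (rather than seconds)
   matches a window "of size 20" with no unit, and centring avoids the
   phase lag that a trailing window would introduce between features
   and BPS timestamps. Statistics are computed on the smoothed series;
   rule order pins smoothing last.

Provenance counters make the conservation law
`in = out + dropped_readjust + dropped_short` checkable on every run,
and on noise-free synthetic sessions the dropped sets are asserted to
match the generator's artifact log exactly.

## Interval statistics and the area around the mean

Every BPS record defines the closed window ±600 s around its
timestamp. Six statistics per feature, 36 in all, describe the window:
mean, min, max, variance, SD, and the area around the mean. The
variance is the *population* variance (divide by \(n\)): the value
describes the observed trace, it does not estimate a sampling
distribution.

The area around the mean captures both the duration and the intensity
of movements: centre the trace on its window mean, split the
piecewise-linear trace at linearly interpolated zero crossings,
integrate each sign-constant piece by the trapezoidal rule, sum the
absolute piece areas, and divide by the summed uninterrupted duration.
Gaps contribute neither area nor duration. Inserting the zero
crossings first (rather than taking per-trapezoid absolute values) is
the geometrically correct reading of "parts that have only positive
values and parts that have only negative values", and a dense-grid
resampling oracle in the tests enforces it to 10⁻⁶ relative error.

The centering mean is, by default, the *time-weighted* (trapezoidal)
mean rather than the raw sample mean: the statistic is an integral
quantity and the sampling rate varies by a factor of three, so a
sample mean would overweight fast-rate stretches. The sample-mean
alternative is available (`mean_method = "sample"`); for the
regularly-sampled fixtures in the tests the two agree.

Windows with zero samples are rejected immediately (`no_data`);
windows with under `min_coverage = 600 s` of cumulative uninterrupted
data are rejected next (`low_coverage`). The two reasons are logged
separately so the data-selection funnel stays inspectable. Coverage is
measured on *preprocessed* segments — those are exactly the data the
descriptor consumes, so a window that nominally contains raw frames
but loses them all to cleaning is correctly treated as uncovered.

## The classifier and its evaluation protocol

The modelling dataset restricts, by default, to the area-around-mean
of AU4s1 and AU4s2 — brow movement is the most common and visible
pain expression — with the full 36-column selection available. The
label is `pain` iff facial BPS ≥ 2.

Evaluation follows a fixed protocol, implemented as a pure function of
(dataset, grid, seed):

- **LOSO-CV**: each subject's windows are scored by a model trained
  on all other subjects; the no-leakage property is asserted
  structurally on every run, and pooled predictions cover each window
  exactly once.
- **Balancing undersampling**: pain windows are rare (on the order of
  1:5), so before each fold's training the majority class is
  subsampled without replacement to the minority count. The draw uses
  a fold-derived seed, so all hyperparameter candidates see identical
  training subsets and reruns reproduce exactly.
- **Standardisation**: per-feature z-scoring fitted on the balanced
  training fold. The descriptor columns are meter-scale quantities of
  very different magnitudes; unscaled distances would be dominated by
  the largest. Switchable off.
- **Tuning**: exhaustive grid — odd \(k\) in 1…21, uniform vs
  inverse-distance votes, Euclidean vs Manhattan distance — scored by
  the pooled-LOSO F1 of the pain class at threshold 0.5. The
  threshold stays fixed during tuning (no nested threshold search);
  ties break toward smaller \(k\), then grid order, for determinism.
- **ROC/AUC**: threshold sweep over unique scores; the trapezoidal
  AUC equals the Mann–Whitney statistic with half credit for ties (a
  brute-force pairwise oracle asserts equality to 10⁻¹²).
- **Bootstrap CI**: 2,000 stratified replicates (resampling within
  each truth class), percentile 2.5/97.5 interval, deterministic
  given the seed. A coverage simulation at a known true AUC (binormal
  scores) attains nominal 95% coverage within Monte-Carlo error.
- **Operating point**: "adjust the threshold to preference" is not an
  algorithm, so the package offers Youden's J (default), a fixed
  threshold, and a sensitivity-floor policy, and reports the
  class-normalised confusion matrix.

KNN inverse-distance weighting handles exact matches by letting
zero-distance neighbours dominate (their label mean is returned),
avoiding the 1/0 singularity.

## The synthetic cohort generator

The generator emulates the acquisition, not the physiology: a
stylised 1,220-point face template (20 × 61 grid over an elliptic
outline with an ellipsoidal dome and nose ridge) with named anatomical
regions; per-subject morphology as a global scale factor drawn from
0.9–1.1; frames at a per-session rate drawn from the profile's rate
range with ±15% interval jitter; isotropic Gaussian coordinate noise
(default 0.2 mm); Poisson-arrival gaps with truncated log-normal
durations; a scrambled readjustment stretch of 0.3–0.5 s after every
gap and at session start; and pain episodes that drive the AU
displacement fields linearly in activation, capped at ~5 mm — a
plausible facial-motion scale, since no published magnitudes exist for
this population. AU4's field pulls the brows toward the nose anchor
and toward each other; the other AUs contract their regions onto their
centroids (with a small anchor-ward pull for the cheek and lip
raisers, whose s1 features would otherwise barely respond). The
recorded facial score quantises the episode amplitude at the
assessment time (`1 + min(3, ⌊4a⌋)`, surjective onto 1–4); an optional
clock-error knob shifts recorded BPS times by up to ±3 min to emulate
paper-and-pencil time notation. A ground-truth log records every gap,
scrambled frame and episode, which is what makes the preprocessing
conformance tests possible.

Under the full-protocol profile (two 8-h sessions/day × 3 days, hourly
assessments) the default gap process removes roughly half the data, so
a substantial share of windows fails the 10-min coverage rule —
mirroring the shape, not the exact numbers, of clinical attrition.
The `"null"` effect profile draws the recorded scores independently of
the episodes that deform the face, giving a label-permutation control
with realistic marginals.

What the generator does **not** emulate: true FACS activation
dynamics, co-articulation between AUs, sedation pharmacology,
non-rigid registration error, or photorealistic geometry. Passing
tests on synthetic cohorts therefore demonstrate that the pipeline
recovers signal that is present and reports chance when it is absent —
they do not certify clinical performance, which requires the (not
publicly available) patient recordings.

## Problem sizes and numerical choices

The test suite and the acceptance script run desk-scale cohorts: 30
subjects × two 10-minute sessions, one assessment every 5 minutes,
±120-s windows with a proportionally scaled 120-s coverage rule, and a
lighter gap process (the `scaled_profile()` defaults; its rate range
is 18–22 Hz around the nominal 20). A strong-effect cohort at these
sizes yields pooled LOSO AUC ≥ 0.9 and the null cohort stays in
[0.4, 0.6]; the bootstrap coverage study uses 200 Monte-Carlo cohorts
of 60 scores per class at 500 replicates. These sizes are the
package's own choice of a configuration whose behaviour is decisive
yet quick to verify; the full-protocol defaults remain in
`cohort_profile()`.

Other pinned numerical details: window clipping is closed on both
ends, and samples outside the window can never influence a statistic
(asserted by mutation tests); segment durations use `t_last − t_first`;
the 20-sample smoothing window places 9 samples left and 10 right of
the centre so interior windows hold exactly 20 samples; degenerate
inputs (empty sessions, all-gap series, single-sample segments,
constant columns under z-scoring, `k` larger than a balanced fold) all
have defined, tested behaviour rather than errors where the protocol
can proceed.

One arithmetic convention deserves a note: the protocol's conventional
measurement total, `protocol_measurement_count()`, counts one
measurement per second of the 48-h protocol (172,800 per patient;
5,184,000 for 30). The raw mesh-frame count at the nominal 20 Hz is 20
times larger and is available as `protocol_frame_count()`.

## Limitations

The default AU subset map is a stand-in defined on the synthetic
template; results on real device streams require the device's own
index sets. The pipeline assumes mesh registration upstream. The
operating point reported by default (Youden's J) is one defensible
choice among several — deployment would pick a policy from clinical
costs. And the binary task deliberately discards intensity
information; with richer data, ordinal modelling of the facial
sub-score would be the natural extension.
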