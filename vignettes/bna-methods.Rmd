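---
title: "Spatiotemporal brain network activation analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatiotemporal brain network activation analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Event-related potentials (ERPs) are stimulus-locked averages of EEG. Their
conventional summaries — peak latency and amplitude at a handful of
electrodes — discard the joint spatial and temporal evolution of the scalp
field. `bna` implements a spatiotemporal alternative: each subject's ERP is
reduced to a small set of *spatiotemporal parcels* (STEPs), each one an
amplitude extremum of the band-limited scalp field together with its
surrounding above-half-amplitude activity in space and time. Aligning and
clustering the STEPs of a cohort yields a group-level *brain network
activation* (BNA) model — a graph whose nodes are group STEPs and whose
edges are latency-synchronization relations — against which individual
subjects can be scored, classified and tracked across visits.

The package targets the 3-stimulus auditory oddball paradigm (Frequent,
Target, Novel stimuli; N100/P200/P300-family components) but nothing in the
pipeline is oddball-specific.

# Pipeline and model

## Pre-processing

1. **Band decomposition.** Each ERP (channels × time, µV) is filtered into
   four conventional bands — δ (0.5–4 Hz), θ (3–8 Hz), α (7–13 Hz), β
   (12–30 Hz) — with a least-squares linear-phase FIR bandpass applied
   forward and then time-reversed, so the net phase is zero and peak
   latencies are not displaced. The deliberately overlapping band edges are
   the conventional ones for ERP work. The filter length defaults to three
   cycles of the band's lower edge (`3 * fs / f_lo` samples), capped at one
   sample less than the record; edges are handled by reflecting one filter
   length of signal at each end.
2. **Scalp grid.** Electrode positions are projected from the head sphere
   by an azimuthal-equidistant projection about the vertex, rescaled to
   grid-fraction coordinates. Each time sample is interpolated from the
   electrodes to a fixed 33 × 37 pixel grid (left-right × anterior-
   posterior; roughly four times 10–20 resolution) with an exact thin-plate
   spline, which reproduces constants and electrode values and is linear in
   the data. Pixels outside the circular head mask are null.

The result is one 3-D amplitude volume (x, y, t) per band.

## Segmentation into STEPs

A *peak* is a voxel strictly greater (positive) or strictly smaller
(negative) than all of its 26 spatiotemporal neighbours inside the mask;
plateaus of exactly equal values count once, at their earliest-time,
lowest-index voxel, and only when the whole plateau strictly dominates its
surroundings. A peak's *STEP* is the 26-connected component, within the
voxels sharing its polarity and reaching half its absolute amplitude, that
contains it. The STEP's *rise time* is the earliest time sample it covers.

Two amplitude floors gate peak detection:

* a noise floor, half the volume's robust noise estimate
  (`0.5 × 1.4826 × MAD`), the default for `detect_peaks()`;
* for cohort analyses (`segment_cohort()`), additionally a *major-event
  floor*: the peak must reach 60 % of its volume's absolute maximum. The
  value is derived from measured filter physics, not tuned: a band-limited
  kernel necessarily rings, and on noise-free simulated components the
  relative amplitude of filter ringing and of cross-band leakage images
  never exceeded ≈ 0.51 of the band maximum, while the weakest genuine
  component in a band stayed ≥ ≈ 0.8. A floor of 0.6 sits between the two
  regimes. It is configurable (`min_abs_frac_max`), and setting it to 0
  recovers pure noise-floor segmentation.

## Group model

Clustering is per band and polarity, in three stages:

1. **Candidates.** Every STEP seeds a candidate cluster that collects, from
   each subject, the STEP whose peak lies within ±50 ms and within 4 pixels
   (Chebyshev) of the seed's peak — the closest by normalised
   spatiotemporal distance `max(|Δt|/50, Δpx/4)` when several qualify.
   Candidates covering < 70 % of subjects are discarded.
2. **Greedy selection.** The candidate with the highest coverage wins (ties:
   smaller mean normalised spread, then earlier seed peak); its members are
   removed from all remaining candidates, coverages are re-evaluated, and
   the process repeats until nothing reaches 70 %. Each STEP joins at most
   one cluster.
3. **Aggregation.** The group peak is the member-wise median location and
   time (rounded to the grid); member voxel sets are aligned to it by their
   own peak offsets; voxels present in ≥ 50 % of members are kept with
   member-mean amplitudes; the group rise time is the earliest kept sample.

**Edges.** For every pair of group STEPs and both synchronization kinds —
peak-time differences and rise-time differences — the per-subject Δt is
computed over subjects contributing to both. An edge is emitted when at
least 70 % of those subjects satisfy |Δt| ≤ 30 ms *and* the common subjects
themselves cover 70 % of the cohort (both gates are configurable; applying
both is the conservative reading of a cohort-level criterion). The edge's
group Δt is the median over the within-window subjects, which keeps the
recorded Δt inside the window by construction. Cross-band edges are
allowed; clusters never mix bands or polarities.

## Scoring a subject

For each group STEP, the subject STEP of the same band and polarity that
satisfies the clustering windows and maximises the topographic correlation
is selected. With `a` the subject amplitudes and `b` the group amplitudes
over the voxel overlap, and means taken per STEP over its own voxels,

* covariance: `cov = Σ (a − ā)(b − b̄)` over the overlap;
* correlation: `cov / sqrt(var_a var_b)` with variances over the overlap —
  exactly 1 against itself, −1 against its negation, and defined 0 when the
  windows are violated, the overlap is empty, or a variance vanishes;
* GFP (global field power): the mean of squared voxel amplitudes of the
  matched STEP (an RMS mode is available; the mean-square form is the
  package default).

Unmatched STEPs contribute 0 to both scores; for each network edge, the
subject's signed peak-time and rise-time differences are added when both
endpoints matched, 0 otherwise. Features are computed against the Target
and the Novel reference model and concatenated. Before classification every
column is z-scored with *training-set* statistics (population SD,
denominator n); zero-variance columns are zeroed and flagged.

## Classification and repeatability

A linear soft-margin SVM (hinge loss, solved in the dual by sequential
minimal optimisation with maximal-violating-pair selection, tolerance
1e-6) separates Target from Novel rows; the signed distance to the plane is
the classification score and ranking quality is summarised by ROC/AUC
(midrank estimator, ties count one half). The default regularization
constant is deliberately tiny, `C = 10^-3.5`: with a few dozen strongly
correlated features and small cohorts, a large margin is preferred over
fitting individual margins.

Test-retest repeatability of each feature uses the one-way random-effects
intraclass correlation, with subject as the grouping factor:
`ICC = (MSb − MSw) / (MSb + (k − 1) MSw)` for `k` visits. Negative values
are reported as computed; a fully degenerate table yields a flagged 0.

# The synthetic oddball generator

Because no reference recordings ship with the package, `simulate_dataset()`
provides a ground-truth world:

* a session is 600 trials at 80 % Frequent / 10 % Target / 10 % Novel,
  256 Hz, epochs −200…800 ms — a standard 3-stimulus oddball session;
* each component is a separable kernel: a 2-D Gaussian over the projected
  montage times a Gaussian-windowed cosine at its band's centre frequency
  (δ 2, θ 5.5, α 10, β 20 Hz). The default set plants a fronto-central
  N100 (−8 µV, 100 ms, θ), a P200 (+7 µV, 180 ms, θ) and a posterior P300
  (+10 µV, 375 ms, δ) for Target, with an earlier (335 ms) and more central
  P300 and a 145 ms N100 for Novel — latencies and topographies in the
  ranges classically reported for this paradigm;
* randomness is layered the way test-retest data vary: a stable per-subject
  amplitude scale and topography displacement, per-visit latency and
  amplitude jitter, and per-trial white noise; a configurable fraction of
  trials receives a ±150 µV square excursion for artifact-rejection tests.

**Envelope width.** The temporal envelope SD is one third of the carrier
period. A wider envelope (more carrier cycles) produces secondary cosine
lobes above the half-amplitude threshold, so a single planted component
would segment into several STEPs; a much narrower one smears the spectrum
across neighbouring bands. One third of a period keeps the kernel unimodal
after band filtering while containing cross-band leakage, and motivates the
0.6 major-event floor above.

**What the generator does not emulate** — and therefore what a green test
does *not* establish: volume conduction and realistic field spread
(components are local Gaussians), 1/f background spectra and spatially
correlated noise, ocular or muscle artifacts with realistic morphology,
component-amplitude correlations across components, and any non-stationarity
within a session. Results on real recordings depend on all of these.

# Numerical choices and conventions

* Strict inequality defines peaks; ties are resolved by the plateau rule.
  Boundary voxels use only their existing neighbours.
* Medians with even counts round half up to the grid; candidate and greedy
  ties break deterministically (spread, then time, then canonical index),
  which makes model building invariant to the order of input STEPs.
* The ±100 µV artifact rule retains samples at exactly ±100 (the rule is
  "outside the range"); the 7-SD epoch rule normalises by a per-channel
  pooled SD; channel dissimilarity uses the median across trials of the
  per-trial correlation with the 4 nearest neighbours' mean, so a minority
  of artifact epochs cannot condemn a channel.
* Signed edge Δt is thresholded on its absolute value; feature Δt keeps the
  sign, ordered by the edge's (a, b).
* All writers emit deterministic output (fixed key order and float
  formats); ERP times are written at full precision so uniform spacing
  survives a round trip, amplitudes at 6 significant digits.

# A caveat on same-subject validation designs

Training a classifier on one visit and testing on later visits of the *same
subjects* is a repeatability-friendly design, but it leaks stable
individual differences: any subject-stable random effect (amplitude scale,
idiosyncratic topography) that differs between the two conditions'
components will separate conditions in training and *replicate* in the test
visits, inflating the null AUC above chance. The package's end-to-end null
test therefore makes the two conditions share the same component
realizations, so Target and Novel rows of a subject differ by trial noise
alone and are exchangeable; simulations with independently drawn (though
identically distributed) per-condition components show exactly the
inflation described. The same caveat applies to real studies validated
across visits rather than across subjects.

# Known limitations

* The greedy clustering is a reconstruction of a three-stage scheme
  (candidate mapping under windows, greedy selection, per-cluster
  aggregation); other reconstructions are possible and all of its knobs are
  exposed.
* STEPs are not merged or split; overlapping parcels from distinct peaks
  are kept as-is.
* The SVM is linear only; no kernels, no hyperparameter search, no
  calibration.
* ICC is the one-way random-effects form only.
* The CLI is a thin convenience layer; programmatic use is the primary
  interface.
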