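---
title: "Closed-loop gaze-contingent fMRI paradigms with flexstim"
author: "flexstim authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Closed-loop gaze-contingent fMRI paradigms with flexstim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flexstim)
```

## The problem

In visual fMRI experiments the measured response depends not only on the
stimulus but on whether the subject actually looked at it. The
conventional remedy — running the full schedule and discarding trials on
which gaze was off target — wastes scanner time and statistical power.
The alternative implemented here is *a priori* adaptation: stimulus
presentation is gated on the subject's measured fixation state, so that
every presented trial is valid by construction. flexstim models this
closed loop end to end at simulated time: an XML experiment description
with adaptive constructs, a scheduler that delays gated trials until the
gating condition holds, online fixation detection from a gaze stream, a
dynamically updated GLM design, and offline analyses that quantify what
the adaptation bought.

## The experiment description dialect

An experiment is a set of *media objects* (the stimuli) plus a
*timetable* of presentation events, extended by five adaptive
constructs:

* **system variables** — named quantities served by external-device
  plugins (here: `eyePosIsFixated`, `eyePosX`, `eyePosY` from a gaze
  provider), identified by a reverse-DNS source string;
* **constraints** — conjunctions of system-variable conditions attached
  to media objects, with *then*/*else* action lists;
* **stimulus actions** — replace the pending stimulus, insert a new
  event (optionally shifting everything that follows by its duration),
  or adapt presentation coordinates;
* **transfer functions** — map a presented trial to a design-matrix
  event (onset offset, duration scaling, parametric weight);
* **dynamic time-based regressors** — design columns populated at
  runtime from the adapted trials and convolved with a haemodynamic
  reference kernel.

`parseExperiment()` reads the dialect (tolerating arbitrary attribute
whitespace and order), `validateRules()` walks every cross-reference and
invariant and returns one message per violation, and
`writeExperiment()` serializes so that parse∘write is the identity on
all modelled fields. An XSD for the dialect ships under
`inst/extdata/edl-schema.xsd`, together with a worked example document.
Times are integer milliseconds from run start and intervals are
half-open `[onset, onset + duration)`. The `length`/`maxLength`
attributes of the dynamic design are read as milliseconds by default;
because other deployments may emit microseconds, the unit is an explicit
argument of `parseExperiment()`. Conditions combine as logical AND only
— the empty conjunction is true — since that is the only combination the
constructs require; richer logic can be layered by nesting constraints
per media object.

## The closed loop

`runClosedLoop()` releases the timetable in onset order against a
registry of provider functions. An unconstrained event is presented at
its planned onset. For a constrained event the constraint is evaluated
at the event's current onset:

* if it holds, the then-actions apply and the event is presented —
  *gating soundness*: a gated event is never shown while its constraint
  is false;
* if not, the else-actions execute. The canonical retry action inserts
  an 8-ms fixation-cross filler and shifts the pending event (and, when
  shifting, all following events) behind it; the constraint is then
  re-evaluated at the end of the filler. The 8-ms filler duration is
  what defines the polling cadence — the engine evaluates at the end of
  each inserted filler rather than continuously during it, a choice we
  make explicit because only the insert-retry loop itself is externally
  specified.

The engine runs on a simulated 1-ms master clock; correctness claims are
about event times, not wall-clock latency, so no real-time sleeping is
involved. By default a gated trial is retried indefinitely (the
procedure modelled never aborts a trial); a `stop` time bounds the run,
and a trial still pending there is logged as abandoned rather than
presented. The event log records, per presentation, planned versus
actual onset, the accumulated delay, the number of fillers spent
waiting, and whether the constraint held at onset. "Planned" is the
schedule as it stands when the event comes up for release: shifts caused
by earlier trials are part of the plan, so `delay` is exactly the
event's own waiting time (filler duration × insertions). Two
conservation properties follow and are tested: the run extends by
exactly the summed filler durations, and the original timetable order is
preserved as a subsequence of the log.

## Fixation identification

Gaze samples are degrees of visual angle with the screen centre at the
origin. Offline segmentation uses dispersion-threshold identification
(I-DT): grow a window until it spans the minimum duration, accept and
extend it while the dispersion metric `(max x − min x) + (max y − min y)`
stays within threshold, otherwise slide by one sample; invalid (dropout)
samples break windows. Defaults follow the study conditions: 200 ms
minimum duration, 1° dispersion threshold, and a centre criterion of 2°
for accepting a fixation as on-target (chosen for stimuli of about 3°
with centre-weighted content).

The online query `isFixated(stream, params, t)` uses the trailing window
of exactly the minimum duration ending at `t`: all samples valid,
dispersion within threshold, centroid within the centre radius. A
trailing window — rather than full I-DT segmentation per query — keeps
the per-query cost constant; the offline definition is the same
criterion applied at the same time points, which is why the offline
compliance recomputation must (and, by test, does) reproduce the online
decisions exactly. If the buffer does not reach back a full window the
query answers `FALSE`: a fixation that cannot be confirmed is not one.
Thresholds are applied in time units, so any sampling rate works; a
calibration helper converts pixel streams given screen geometry.

## The paradigm generator

`generateSchedule()` builds the 2×2 paradigm (negative/neutral ×
adapted/non-adapted): every picture appears exactly twice, once per
adaptation condition, in an intermixed pseudo-random order; pictures
last 500 ms; inter-trial intervals are drawn from {4.00, 4.75, 5.50,
6.25} s. The printed interval description ("4 to 6.25 s in steps of
1 s") is arithmetically inconsistent, so we honour the endpoints with
four equally spaced values and leave the set configurable. Which
condition a picture meets first is decided by
`selectRandomization()`: 1000 random divisions of each class into
first-shown-adapted versus first-shown-non-adapted halves are scored by
the absolute difference in mean valence over the negative class — the
first reaction to a negative picture is the sensitive quantity — and the
argmin is kept (ties to the earliest candidate). Diagnostics report the
achieved mean difference, the spread of candidate scores, and the
difference in valence spread of the selected halves, since the
published spread criterion (< 0.1) does not say which of the two it
constrains. Adapted trials reference the fixation constraint; each
(class, condition) cell feeds its own dynamic regressor through an
impulse transfer function.

## Design matrices and the GLM

A presented trial maps through its transfer function to a regressor
event; a duration scale factor of 0 yields impulse (event) modelling,
which is how 500-ms pictures are modelled here. Events are laid on a
100-ms microtime grid, convolved with the haemodynamic kernel, and
downsampled at scan times (TR 2 s by default). The 100-ms default
resolves the 8-ms onset shifts after they accumulate to a grid step
while keeping cost negligible; it is configurable where finer
quantization matters. The kernel is the canonical difference of gammas
(peak 5.4 s from shape 6 × scale 0.9 s, undershoot 10.8 s from shape
12 × scale 0.9 s, undershoot ratio 0.35), peak-normalized to 1 on a
dense grid — a line search is deliberately avoided because the
difference of gammas is not unimodal. Only the kernel's name is
externally specified, so all parameters are overridable through
`hrfParams()`. Derivative columns convolve the same event indicator
with finite-difference kernels; `scaleHeightToZeroMean` is read as
per-column mean-centring. Nuisance covariates (e.g. motion parameters)
are accepted as a numeric table; estimating them is out of scope.

`fitGlm()` is ordinary least squares per voxel with Student t contrasts
(`contrastTMap()`), thresholded by the user at uncorrected p values as
is customary for this design; no multiple-testing correction is applied.
The first `ignoreScansAtStart` scans (default 20 at TR 2 s) are
discarded before fitting. The incremental path (`glmAccumulator()`,
`addScans()`, `glmEstimates()`) accumulates X′X, X′Y and Y′Y so that the
fit after scan *k* equals the batch fit on the first *k* scans to
1e-10 relative tolerance — the property that makes runtime design
updates exact rather than approximate. Rank-deficient designs fall back
to a pseudoinverse with degrees of freedom reduced to the rank, with a
warning.

## What the generators emulate — and what they do not

`simulateGaze()` draws a two-state semi-Markov subject: centre-fixation
epochs and eccentric-resting epochs with exponential dwell times whose
means are `compliance × meanCycle` and `(1 − compliance) × meanCycle`,
so the long-run probability of being centre-fixated at a scheduled check
equals the compliance parameter by construction. Within an epoch gaze
jitters around the resting point with SD 0.05° (fixational jitter small
enough that a 200-ms window stays within the 1° dispersion threshold);
eccentric resting points are uniform on 3–8° so that off-centre epochs
form genuine but off-target fixations. Dropout flags samples invalid
independently at a configurable rate (default 0). The default sampling
rate is 60 Hz; the study hardware's rate is not externally specified.
The compliance range of interest spans roughly 0.49–0.83, the
low/high-compliance group means reported for this kind of cohort, and
the generator covers it by a single parameter. Deliberately *not*
modelled: saccade kinematics, smooth pursuit, blink interpolation,
head-motion-induced drift, and physiological noise. Passing tests
therefore show that the adaptation logic, timing bookkeeping and
statistics are correct under a subject whose compliance is exactly
known; they do not certify detection performance on real oculomotor
data.

`simulateBold()` generates `Y = baseline + Xβ + ε` with AR(1) noise of
configurable lag-1 autocorrelation — enough structure to exercise
estimator calibration (type-I error, coverage) without claiming
realistic fMRI noise spectra.

## Numerical and design choices

* Integer-millisecond event times; ties in the log are ordered by
  actual onset with fillers sorted before the trial they delayed.
* Median split on non-adapted valid fraction: subjects are stably
  sorted and the lower half (`floor(n/2)`) forms the Low-Compliant
  group, so the median subject of an odd cohort is High-Compliant —
  the convention that reproduces a 9/8 split at n = 17. Tie handling
  (stable input order) is a documented convention, not an inference
  about the original analysis.
* Time-to-valid curves report, per condition, the onset of the
  `⌈p·N⌉`-th valid trial; unreached fractions are flagged, never
  extrapolated. Trials whose onset window lacks gaze coverage are
  indeterminate: excluded from denominators and reported separately,
  mirroring how signal-loss subjects are excluded rather than counted
  invalid.
* Then-branch insert actions are honoured but cannot delay the event
  whose constraint just passed; they insert after it. Only the
  else-branch retry is externally evidenced; the symmetric branch
  exists for completeness.
* Degenerate inputs: empty condition lists evaluate true; empty
  regressors sample to zero columns; an empty gaze stream never
  confirms a fixation; empty rating tables are rejected.

## Problem sizes used in the shipped tests

The test suite exercises the full 60+60-picture paradigm for structural
checks and randomization matching, and smaller cohorts (1–15 pictures
per class) for repeated closed-loop simulation, chosen so the complete
suite runs comfortably on a laptop: the brute-force I-DT oracle is
quadratic and is run on streams of at most 500 samples, calibration
checks use 500–1000 simulated voxels/replicates, and the
`scripts/acceptance.R` run drives the full 240-trial paradigm once
against a 50%-compliant subject. These sizes are the package's own
choices for a fast, deterministic test bed.

## Known limitations

Rendering, device drivers and scanner transport are out of scope: the
closed loop runs at simulated time against provider functions, and the
multi-process architecture of a production system is modelled as module
boundaries within one process. Pre-processing (realignment, slice
timing, normalization, smoothing, high-pass filtering) is assumed done;
the GLM accepts whatever time series it is given. Second-level group
statistics are not implemented — the compliance report and median split
produce the per-subject quantities such analyses would consume.
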