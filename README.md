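# flexstim

Closed-loop, gaze-contingent stimulation paradigms for fMRI — described,
simulated, scheduled and analysed in one R package.

## The problem

fMRI responses to visual stimuli are confounded by whether the subject
actually looked at them. Discarding badly fixated trials after the fact
wastes scanner time and power; the alternative modelled here is *a
priori* adaptation: each gated trial is presented only once the subject
fixates the screen centre, so every presented trial is valid by
construction. flexstim implements the full loop at simulated time:

* an XML **experiment-description dialect** with adaptive constructs —
  constraints over device-served *system variables*, stimulus actions
  (replace / insert-and-shift / reposition), transfer functions, and
  dynamic time-based regressors (`parseExperiment()`,
  `validateRules()`, `writeExperiment()`; XSD in `inst/extdata/`);
* a **closed-loop scheduler** (`runClosedLoop()`): a constrained event
  is evaluated at its onset; while the constraint fails, an 8-ms
  fixation-cross filler is inserted and the event (plus everything that
  follows) shifts behind it, until the subject fixates;
* online and offline **fixation identification**: dispersion-threshold
  (I-DT) segmentation with the Salvucci–Goldberg metric
  (Δx + Δy ≤ 1° over ≥ 200 ms) and a 2° centre criterion
  (`idtFixations()`, `isFixated()`);
* a **dynamic GLM pipeline**: trials map through transfer functions to
  regressor events, are convolved with the canonical double-gamma
  haemodynamic kernel on a 100-ms microtime grid, and fitted by
  ordinary least squares with Student-t contrasts
  — batch (`fitGlm()`) or incrementally, with the incremental fit equal
  to the batch fit after every scan (`glmAccumulator()`);
* seeded **synthetic subjects**: a two-state semi-Markov gaze model
  whose long-run centre-fixation probability equals a compliance
  parameter (`simulateGaze()`), and AR(1) BOLD simulation
  (`simulateBold()`);
* **offline analyses**: per-condition compliance with online/offline
  consistency validation (`compliance()`), High-/Low-Compliant median
  split (`medianSplit()`), and time-to-valid-trials curves
  (`timeToValid()`).

In the 2×2 picture paradigm (`generateSchedule()`), 60 negative and 60
neutral pictures each appear twice — once adapted, once non-adapted —
for 500 ms with inter-trial intervals from {4.00, 4.75, 5.50, 6.25} s;
which condition comes first is chosen by scoring 1000 randomizations
for minimal mean-valence difference of the negative first-presentation
halves (`selectRandomization()`).

## Worked example

```r
library(flexstim)

ratings <- syntheticRatings(60, 60, seed = 1)
sel <- selectRandomization(ratings, nCandidates = 1000, seed = 1)
sel$diagnostics$meanDiff
#> [1] 8.219624e-05          # best of 1000 candidate divisions

spec <- generateSchedule(ratings, seed = 1)
spec
#> ExperimentSpec
#>   media objects     : 241
#>   timetable events  : 240
#>   system variables  : 1
#>   constraints       : 1
#>   transfer functions: 1
#>   dynamic regressors: 4
#>   TR 2000 ms, ignoreScansAtStart 20

gaze <- simulateGaze(gazeModel(compliance = 0.5), duration = 2.1e6,
                     seed = 2)
log <- runClosedLoop(spec, list(org.flexstim.gaze = gazeProvider(gaze)),
                     stop = max(gaze$t))
log
#> EventLog
#>   entries : 18355 (18115 inserted fillers)
#>   adapted : 120, mean delay 1207.7 ms
#>   run end : 1.50392e+06 ms

compliance(log, gaze)
#> Fixation compliance report
#>    condition nTrials validFraction meanDistance meanDelay nIndeterminate
#>      adapted     120          1.00   0.06173019  1207.667              0
#>  non_adapted     120          0.45   2.92008038     0.000              0
#> online/offline adapted-trial flags consistent: TRUE
```

A half-compliant subject fixates on 45% of the uncontrolled (non-adapted)
presentations, but the gated condition reaches 100% validity — the
closed loop waited a mean 1.2 s per adapted trial (151 × 8-ms fillers on
average) instead of losing the trial. `timeToValid()` turns the same log
into time-to-p%-valid-trials curves per condition: with this subject the
non-adapted condition never reaches 50% valid trials, while the adapted
condition reaches any fraction. From here, `buildDesignMatrix()` +
`fitGlm()` + `contrastTMap()` take the adapted onsets into a GLM t-map,
and `runPipeline()` runs all stages with one seed and a manifest
(`inst/scripts/flexstim` wraps everything for the shell: `validate`,
`paradigm`, `simulate`, `run`, `glm`, `report`, `pipeline`).

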