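---
title: "Evaluating myoelectric prosthesis control from functional-task recordings"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating myoelectric prosthesis control from functional-task recordings}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(promet)
```

## The problem this package addresses

Pattern-recognition myoelectric prostheses classify surface EMG from the
residual limb into hand and wrist commands. Task scores and completion times
alone say little about *how* a controller behaved: whether the user fought
the device with repeated open/close corrections, hesitated with the hand
held open before a grasp, or had to freeze the arm to get a clean wrist
rotation. A particular failure mode, the **limb position effect**, degrades
classification when the arm occupies positions (typically raised ones) that
were under-represented in training, because gravity load, accessory muscle
activity and electrode shift all alter the EMG patterns.

`promet` implements a quantitative evaluation suite for two-controller,
repeated-measures study designs built on standardized object-relocation
tasks — the Pasta Box Task and the Refined Clothespin Relocation Test (Up
and Down variants), each consisting of three object-transport movements per
trial, each movement subdividing into Reach, Grasp, Transport, Release and
Home phases. It provides:

1. a canonical data model and CSV/JSON I/O for trial recordings;
2. signal conditioning (EMG filtering, resampling, windowing, smoothing,
   differentiation, motor-to-kinematics polynomial recalibration);
3. speed-threshold segmentation of trials into movements, phases and the
   Reach-Grasp / Transport-Release movement segments;
4. task-performance metrics (success rate, trial/phase durations, peak hand
   velocity, hand distance travelled, between-trial hand trajectory
   variability);
5. control-characteristics metrics (grip-aperture and wrist-rotation
   excursion, adjustment counts, grip-aperture plateau, simultaneous
   wrist-shoulder movement, baseline-normalized total muscle activity);
6. rule-based identification of limb-position-effect instances from
   across-participant medians and IQRs;
7. the statistical comparison pipeline (repeated-measures ANOVA with
   Greenhouse-Geisser correction, Friedman fallback, gated paired
   t / Wilcoxon tests, survey aggregation);
8. a synthetic trial/cohort generator with an analytic ground-truth ledger,
   so that every metric and the rule-based identifier are testable without
   access to any participant data.

## Data model and units

A trial (`trial_recording()`) carries kinematics at 120 Hz (hand position
in mm, grip aperture in mm, wrist rotation and shoulder flexion/extension
in degrees), task-object positions at 120 Hz, 8-channel surface EMG in
[-1, 1] at 200 Hz, and optionally raw motor positions at 50 Hz. Time is
expressed in trial seconds with the first kinematic sample at t = 0; all
boundaries downstream use that clock. Missing kinematic samples are NaN and
propagate; a required channel with more than 5% missing samples fails
validation, since marker-gap reconstruction is out of scope here. The
`error_free` flag is an observational input (drops, wrong sequence and
similar task errors are judged by the experimenter), never computed.

## Signal conditioning choices

* **EMG filtering.** 4th-order Butterworth high-pass at 20 Hz (movement
  artifact) plus a constrained biquad notch at 60 Hz with quality factor 30
  (mains), both applied forward-backward so phase is preserved — event
  timing feeds the segmentation, so zero phase matters more than magnitude
  ripple.
* **Resampling.** Previous-neighbour (sample-and-hold) upsampling aligns
  50 Hz streams with 200 Hz EMG; linear interpolation brings 50 Hz motor
  positions to the 120 Hz kinematic clock before calibration.
* **Windowing.** Classification-style analysis windows default to 160 ms
  with a 40 ms offset; the count follows `floor((N - L)/S) + 1`.
* **Smoothing.** Velocity-based metrics use a centered moving average with
  a 0.1 s window (13 samples at 120 Hz, rounded to odd). The window length
  is a package choice — it suppresses sample jitter without hiding real
  control adjustments — and is configurable per analysis because adjustment
  counts depend on it. Edges truncate (shrinking window) rather than
  zero-pad, avoiding spurious edge dips that would read as sign changes.
* **Differentiation.** Central differences with one-sided endpoints. For
  peak-velocity metrics, positions are additionally low-passed at 6 Hz
  (zero phase) first, because speed peaks are noise-sensitive. The
  zero-phase filter uses odd-reflection end padding; without it, filter
  transients at segment edges can dwarf genuine peaks on signals with large
  endpoint offsets.
* **Motor recalibration.** Grip aperture is regressed on hand-motor
  position with a degree-3 polynomial and wrist angle on wrist-motor
  position with degree 2 (the smallest classes that absorb the hardware's
  mild nonlinearity), after linear upsampling to 120 Hz.

## Segmentation

The movement structure is detected from speeds, with every threshold in
`segmentation_config()`:

* An **object-transport bout** is a run where the composite object speed
  (per-sample maximum over tracked objects) exceeds 5% of its trial peak;
  runs closer than 0.2 s merge; exactly three bouts must remain.
* A **movement** extends from the onset of the hand motion preceding its
  bout (hand speed rising past 5% of the trial peak) to the offset of the
  hand motion following it (the return toward home).
* Within a movement, **Transport** spans the object-speed run above 5% of
  the in-window peak; **Grasp** runs from the hand's arrival at the object
  (falling below the hand threshold) to Transport onset; **Reach** from
  movement start to Grasp onset; **Release** from Transport end to the
  hand-retreat onset (the next rising crossing after the hand has settled);
  **Home** is the remainder and is detected but never analyzed.

Boundaries snap to sample timestamps — all downstream metrics are
sample-sum based, so sub-sample interpolation would buy nothing. Phases
shorter than `min_phase_s` (default 0.05 s) are retained with a warning; a
movement in which the hand never decelerates before Transport raises an
error, as no Grasp onset exists.

## Metric definitions worth spelling out

* **Hand velocity** is the magnitude of the 3D velocity vector (a single
  scalar per segment), not a signed component.
* **Hand trajectory variability** time-normalizes each trial's x, y, z to
  101 points over 0-100% of the segment (linear interpolation), takes the
  across-trial sample standard deviation (n - 1 denominator; with at most
  ten trials per condition the denominator choice is material and the
  two-trial closed form `offset/sqrt(2)` pins it) per coordinate and point,
  averages the three SDs per point, and reports the maximum.
* **Relative phase duration** divides by the Reach-through-Release span;
  Home is excluded from the denominator.
* **Adjustment counts** use the sign of the smoothed velocity with a dead
  band: samples whose speed is at most 1% of the in-window peak count as
  sign zero. Exact zeros have measure zero in real signals, so without a
  dead band the 0-state would be unreachable; the 1% default is pinned by
  parameter-recovery tests on trials with known injected reversal counts.
  Transitions 0→+, 0→−, −→+ and +→− are counted; transitions into 0 are
  not.
* **Grip-aperture plateau** takes smoothed aperture ≥ 90% of the segment
  maximum AND smoothed |velocity| ≤ 10% of the segment maximum, inclusive.
  The inclusive reading makes the degenerate all-zero-velocity case — a
  hand held perfectly open — a full-segment plateau, which is semantically
  right even though a literal strict reading would return zero.
* **Simultaneous wrist-shoulder movement** uses strict `>` thresholds at
  10% of the movement maxima of the two smoothed angular speeds and is
  computed only for phases that require both functions (Reach and Transport
  of the clothespin tasks).
* **Total muscle activity** filters and rectifies the EMG, subtracts each
  channel's mean rectified rest-class value (rest recorded with the elbow
  at 90 degrees), sums across channels, low-passes the sum at 6 Hz (zero
  phase) as a linear envelope, and sums the envelope samples over the
  phase. Negative post-subtraction values are kept by default (the literal
  reading of the definition); `clip_negative_activity` clips them at zero.

## Limb-position-effect identification

For each controller × task × phase × control-characteristics metric, trial
values are averaged per participant and movement, then across-participant
medians and IQRs (Q3 − Q1, linear-interpolation quantiles) are taken per
movement and rescaled to percent of the maximum across movements 1-3
(medians and IQRs independently). Rule tables then flag an instance only
when *all* conditions in a row hold; equality with 100% is tested to 1e-9,
so ties — two movements both at the maximum — both satisfy it. Blank cells
impose no condition. Three design points deserve emphasis:

* **Larger-is-better inversion.** The simultaneity metric improves upward,
  so its rescaled medians are subtracted from 100% (becoming "share of the
  phase without simultaneous movement"). After subtraction the rules'
  `= 100%` conditions would essentially never hold, so the package
  re-rescales the inverted medians to percent of their new maximum before
  rule evaluation. That re-rescaling is this package's choice among the
  readings the procedure admits, not an asserted property of any external
  protocol; it is the only reading under which the rule set remains
  applicable to inverted metrics.
* **Minimum-contrast guard.** Re-rescaling amplifies whatever spread
  exists. If all inverted medians lie within 5 percentage points of zero
  (the movements were practically identical), the statistic is marked not
  evaluable instead — otherwise sampling noise of a homogeneous cohort
  would be blown up to the full 0-100 range and rules could fire on data
  with no real position effect. The 5-point floor was chosen as clearly
  below any practically meaningful degradation and is a parameter of
  `invert_larger_is_better()`.
* **Rule routing.** The pasta task has two rule options; by default the
  Reach/Grasp option is applied to Reach and Grasp phases and the
  Transport/Release option to Transport and Release phases, with a switch
  (`pasta_both_everywhere`) to apply both options to every phase. The
  clothespin tasks use their single rule. Degenerate statistics (all
  medians zero, or all IQRs zero) are not evaluable and never flag.

## Statistical comparison

Phase- and segment-level metrics are first averaged over trials and
movements per participant. Normality is decided by Shapiro-Wilk (α = 0.05)
on the phase-centered controller differences — the test is unnamed in most
protocols, and Shapiro-Wilk is the conventional small-sample choice. The
normal branch runs a fully within-subject controller × phase ANOVA; each
effect's F uses an orthonormal contrast basis and its Greenhouse-Geisser
epsilon is `tr(S)^2 / (q tr(S^2))` of the contrast covariance, with
epsilon-scaled degrees of freedom (for any two-level factor epsilon is
identically 1). Pairwise paired t-tests per phase run only when the
controller effect or the interaction passes α = 0.05. The non-normal
branch gates pairwise Wilcoxon signed-rank tests on a Friedman test; with
two controllers the Friedman blocks are participant × phase cells and the
treatments are the controllers, which focuses the gate on the controller
factor (with k = 2 the statistic reduces to a sign-test-like quantity).
Trial-, task- and controller-level metrics skip the omnibus and go straight
to the pairwise test. Zero-variance differences report p = 1 with a
degenerate flag rather than erroring. No across-metric multiplicity
correction is applied; the report says so explicitly, and survey dimensions
(NASA-TLX 0-100, usability 0-5) are aggregated as per-dimension medians and
IQRs with paired Wilcoxon tests.

## The synthetic generator and its ground truth

`generate_trial()` scripts a trial from closed-form pieces: minimum-jerk
hand paths between home, source and destination locations (approximate
task layouts; only the relative structure matters to the metrics),
aperture open/plateau/close/release ramps, wrist and shoulder ramps with a
controllable overlap fraction, objects that follow the hand during their
transport, and EMG synthesized as rest noise plus amplitude-modulated
bursts during the effortful phases — amplitude structure only, with no
physiological claim. Degradation knobs per movement emulate the limb
position effect the way it presents in recordings: extra aperture/wrist
adjustment reversals (Poisson across trials, so spread grows with the
mean), longer plateaus, larger path noise, scaled wrist excursions,
reduced simultaneity overlap and higher EMG effort, all increasing toward
movement 3 in the degraded arm of a generated cohort.

The **ground-truth ledger** records, per movement, both the scripted phase
boundaries and the *threshold-consistent* boundaries: a minimum-jerk ramp
spends its first ~6% below a 5%-of-peak speed threshold, so no threshold
detector can ever report the scripted onset. The detectable boundaries are
closed-form crossing times of the analytic speed profiles, computed
independently of the sampled-signal detector; recovery tests compare the
detector against them. Ledger values for plateau and simultaneity apply
the metric's own definitional smoothing (a centered moving average whose
width equals the effective 13-sample window at 120 Hz) to the *continuous*
analytic signals on a fine grid — the smoothing is part of the metric
definition, not an implementation artifact — and the simultaneity
percentage is evaluated on the 120 Hz sample grid, since a ratio of sample
counts is what any finite recording yields. Injected adjustment counts are
exact bookkeeping: each scripted ramp contributes one transition, and
wiggle trains are placed with margins wider than the smoothing window so
that a dead-banded sign sequence sees each reversal exactly once.

What the generator does *not* emulate: marker dropout and occlusion,
soft-tissue artifact, EMG crosstalk and electrode-shift dynamics,
within-trial learning, or compensatory trunk motion. Tests passing on
generated cohorts therefore validate the *computational pipeline* —
segmentation, metric arithmetic, rule logic, statistics — under known
ground truth; they do not validate the metrics' clinical sensitivity on
real recordings.

## Problem sizes and numerical tolerances used by the test suite

The parameter-recovery and discrimination checks run on a generated
two-arm cohort of 8 participants × 3 tasks × 10 trials (480 trials) with
path noise at zero (recovery of counts is defined at zero noise);
segmentation agreement uses 200 random-parameter trials; the
no-degradation false-positive sweep uses 20 smaller cohorts (4-6
participants, one task, 2-3 trials) — sizes chosen to exercise every code
path at full scale once and the stochastic sweeps at a scale that keeps
the whole suite comfortably re-runnable. Recovery tolerances: adjustment
counts exact; plateau within 0.1 s (observed error ≈ 0.01 s); simultaneity
within 2 percentage points (observed ≈ 1.6); boundaries within 2 samples
at 120 Hz. Oracle-equivalence checks (adjustment counting, rule
evaluation, Friedman statistic) are exact over 1,000 / 10,000 / 200
random cases respectively.

## Known limitations

* The segmentation assumes the canonical three-movement structure; trials
  with aborted or extra transports are rejected rather than repaired.
* The rule thresholds for limb-position-effect identification are fixed
  configuration constants; re-deriving them from data is explicitly out of
  scope.
* The RMANOVA is implemented for the fully within-subject two-controller
  design only — no between-subject factors, no missing cells.
* `error_free` must be supplied; the package does not attempt to detect
  task errors from the signals.
* Survey handling aggregates scores; administering instruments is out of
  scope, and NASA-TLX dimensions are used raw (no weighted pairwise
  procedure).
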