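---
title: "Daily-life gait analysis and fall-risk model selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Daily-life gait analysis and fall-risk model selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dailygait)
```

## The problem

People with Parkinson's disease fall often, and fall history alone is a blunt
predictor of who will fall next. Week-long passive monitoring with three
inertial sensors — one on each foot, one over the lumbar spine, sampling
tri-axial acceleration and angular velocity at 128 Hz — captures how a person
actually walks and turns at home. `dailygait` implements the full analysis
chain for such recordings: raw streams are segmented into gait bouts, strides
and turns; a subject-week is reduced to a catalog of 52 digital gait measures
in four domains; and an exhaustive best-subsets logistic regression, screened
by BIC and ranked by empirical AUC, searches for small combinations of
measures that discriminate future fallers from non-fallers.

Because raw clinical recordings of this kind are rarely shareable, the package
carries a first-class synthetic-data module with two tiers: a **ground-truth
event timeline** (every bout, stride and turn with its commanded parameters)
and a **signal renderer** that turns a timeline into the three IMU streams.
Every stage of the pipeline can therefore be verified twice — exactly against
the event tables, and with tolerances against detections from rendered
signals.

## The detection pipeline

**Foot angles.** Foot pitch (sagittal inclination, positive toe-up) is
strapdown-integrated from the pitch gyro, re-anchored at every foot-flat
interval (gyro magnitude below 8 deg/s for at least 0.05 s) to the
accelerometer inclination. Heading is integrated from the gravity-axis gyro
component; its slow drift is harmless because heading enters only through
within-stride changes and toe-out relative to the travel direction. Foot roll
is treated as negligible for a flat-mounted sensor.

**Steps.** Swing phases appear as positive pitch-velocity bumps. Peaks above
an adaptive threshold — 20% of the 90th-percentile amplitude in 10 s blocks,
floored at 30 deg/s so quiet periods yield nothing — mark swings; toe-off and
heel-strike are the flanking zero crossings, refined to sub-sample precision.
The swing-peak instant is located by projecting both locally linear flanks of
the velocity peak to their zero crossing, which stays accurate even when the
commanded mid-swing pitch sits close to the foot-strike pitch and one flank
is shorter than the sample spacing.

**Bouts.** Steps from both feet are merged into one time-ordered sequence
(the chaining rule speaks of consecutive steps, not consecutive steps of one
foot). Runs with inter-step gaps strictly under 2.5 s become candidates, and
candidates are kept as gait bouts only if they last at least 3 s from first
to last step and contain at least 3 steps. Bout duration is measured
first-step-to-last-step, which avoids inventing a padding constant.

**Strides.** A stride runs between consecutive same-foot heel-strikes. Stance
is heel-strike to the same foot's next toe-off; double support sums the
intervals with both feet grounded; mid-swing pitch is read at the swing-peak
instant; the foot-strike angle at heel-strike; the toe-off pitch at (and its
maximum within ±0.1 s of) toe-off. Stride length, swing elevation and lateral
excursion come from ZUPT-aided double integration of foot acceleration
between foot-flats — these are the least-validated outputs of the pipeline
and are labelled as such. Toe-out is the stance heading minus the
displacement direction of the stride's swing, which stays meaningful inside
turn-containing bouts where a bout-level travel heading would not.

**Turns.** The lumbar yaw rate (gyro projected on the gravity axis estimated
from low-passed acceleration; the projection is exact for yaw up to a small
roll-rate leakage) is low-pass filtered at 1.5 Hz for detection: candidates
start and end at 5 deg/s crossings around excursions beyond 15 deg/s,
same-direction candidates closer than 0.1 s merge, and candidates survive
only with an integrated amplitude above 40 degrees and a duration in
[0.5, 10] s. Boundaries are then refined on the unfiltered signal and the
angle integrated there, since the low-pass smears sharp flanks. Only the
40-degree amplitude rule is a scientific constant of the analysis; the
remaining thresholds are detector implementation constants, and all of them
are exposed in `dailygait_config()`.

**Straight walking.** A stride counts as straight if its heading changed by
no more than 20 degrees (stance-to-stance; the boundary value still counts)
and it does not overlap a detected turn. Only straight strides feed the
stride-derived measures.

## The measure catalog

`measure_catalog()` returns 52 entries: 16 Lower Body stride quantities
(cadence, stride time, step duration, stance/swing/single-support/
double-support percentages, gait speed, stride length, swing elevation,
foot-strike angle, toe-off pitch and its local maximum, mid-swing pitch,
toe-out, lateral swing excursion) summarised by their mean; 6 Lower Trunk
quantities (coronal/sagittal/transverse range of motion and peak angular
velocity per stride); 8 Turning measures (mean and variability of turn angle,
duration, peak velocity and steps per turn); and 22 Variability entries — the
stride-to-stride dispersion of the 16 + 6 stride quantities. Variability is
the sample standard deviation by default (`variability = "cv"` switches to
the coefficient of variation); SD is the natural reading when toe-out
variability is reported in degree-like units. Stance-time and double-support
variability are carried by the percent-of-gait-cycle entries
(`stance_pct_sd`, `double_support_pct_sd`), since the Lower Body quantities
are defined as percentages. All straight strides of both feet across the
whole week pool with equal weight per stride; a subject with no straight
strides gets missing values, never zeros. Left and right feet are pooled into
one stride population; per-side analysis can be done by filtering the stride
table's `side` column.

## The fall-risk screen

`label_fallers()` turns a falls log (6-month retrospective count plus
two-week prospective reports over a year) into past-faller (≥ 1 retrospective
fall), future-faller (≥ 1 prospective fall) and recurrent-faller (≥ 2) labels;
near-falls never count, and incomplete follow-up marks labels provisional.

`best_subsets()` is the modelling core. Every subset of 2, 3 and 4 measures
is fitted by maximum-likelihood logistic regression (IRLS, convergence at
`max |Δβ| < 1e-8` within 100 iterations) on z-scored predictors, and the 15
lowest-BIC converged models per size are retained — 45 in all, with BIC
`= −2 logL + p log n`, `p` counting the intercept and `n` the complete-case
subjects. Retained models are scored by the empirical AUC of their linear
predictor (pair counting with ties at one half, identical to the trapezoidal
area under the empirical ROC), given a stratified bootstrap percentile 95%
interval (2000 resamples within class, seeded), and the 10 highest-AUC models
are ranked; AUC ties break by lower BIC, then lexicographically. The object
reports how often each measure appears across the ranked models. Separated
fits are flagged but kept — with 34 subjects and strong measures
near-separation is expected, and the likelihood (hence BIC) remains well
defined at the iteration cap; no ridge or Firth penalty is applied by
default. `power_sample_size()` completes the statistical module with an exact
noncentral-t sample-size search (one-sided by default, with a message;
`sided = "two"` is a parameter).

## The synthetic cohort

`cohort_spec()` fixes the study design: 17 fallers and 17 non-fallers, 7 days
of at least 8 wear hours (9.2 by default, matching roughly 64 total hours
over a week), 128 Hz. Activity is generated as a renewal process of gait
bouts (7.8 per wear hour) whose sizes are log-normal in steps (calibrated so
the cohort averages about 155 strides per hour, between the reported group
means), and turns at 20 per hour, 60% of them taken while walking. Walking
turns span whole gait cycles, so the strides they cover are flagged as
turning; standalone turns sit between bouts. Heading evolves only through
turns. Commanded turn magnitudes are truncated at 45 degrees so that
commanded and detectable turns coincide; the detectors are separately shown
never to emit 20–35 degree rotations.

Stride-level parameterisation was chosen over joint-space biomechanics: every
catalog measure is a stride or turn summary, so drawing stride time, stance
fraction, pitch landmarks, toe-out and swing geometry per stride (subject
latent mean plus independent Gaussian within-subject noise; latent means and
within-subject SDs drawn per subject from group distributions) gives exact
oracles for every stage. Group effects sit by default on mid-swing pitch and
peak turn velocity (lower in fallers) and on toe-out stride-to-stride SD
(higher in fallers), each at about 1.5 between-subject SDs, with milder
effects on pace and trunk motion. Future-faller status is drawn from a
logistic link on the standardized subject latents (`outcome$mode =
"logistic"`); `mode = "group"` ties the label to the design group, which is
what the planted-recovery experiments use so that the advertised effect sizes
are exactly the label-group effect sizes.

The renderer produces signals whose strapdown integrals reproduce the
commanded quantities: the swing pitch-velocity bump is a two-piece sinusoid
that peaks exactly where the pitch passes the commanded mid-swing angle and
meets zero with non-zero slope (sharp toe-off/heel-strike landmarks); turns
are trapezoidal yaw-rate profiles with 30% ramps; trunk oscillation runs at
the stride frequency with the commanded range of motion, suppressed through
turns so the turn integral is clean (the stride immediately before a turn
loses a fraction of its oscillation window — a known, sub-percent bias on
trunk measures); foot translation renders commanded stride length, swing
elevation and lateral excursion along the travel direction; accelerometers
measure gravity in the sensor frame plus movement acceleration. Noise is
white (0.03 m/s², 0.5 deg/s per sample) plus a constant per-day gyro bias
(SD 0.05 deg/s).

What the generator does **not** emulate: freezing-of-gait and festination,
tremor, stair and incline walking, sensor mounting variation, magnetometer
channels, and non-wear detection (nights are simply absent, mirroring
sensors-off-at-night). Passing tests therefore show that the pipeline
recovers what this generative family produces — clean cyclic gait with known
event structure — not that it is robust to every artefact of real
free-living data.

## Numerical choices

Integration is trapezoidal throughout (a rectangle rule leaves a half-sample
phase lag that corrupts the ZUPT trajectory at 128 Hz). Event times are
interpolated to sub-sample precision; pitch reads interpolate linearly
because angle slopes reach ~200 deg/s. The ZUPT trajectory integrates only
over the movement window between flat intervals, with linear velocity-drift
removal anchored at zero velocity on both ends — integrating across long
idle stretches would leak drift into the displacement direction that toe-out
is measured against. Degenerate inputs follow one rule: empty in, empty out
(empty cohorts, motionless streams, zero-activity timelines), while
contradictory inputs (negative SDs, non-monotone timestamps, a lumbar stream
passed to a foot function, constant outcomes) raise errors.

## Problem sizes used by the test-suite

The tests exercise the same code paths as a full week at reduced scale,
chosen so the suite runs in minutes: rendered recordings of 7–25 minutes
(single subjects, 20-subject noise panels), ground-truth cohorts of 17 + 17
subjects over 1–3 monitoring days, 50-replicate screening experiments at 12
candidate measures, and 1000-case brute-force equivalence sweeps for the bout
rules. Subject-level measure precision at 2 monitoring days is already
dominated by between-subject variance (thousands of strides per subject), so
the discrimination experiments lose essentially nothing relative to a full
week.

## Known limitations

Stride length, gait speed, swing elevation and lateral excursion rest on
double integration and are the least validated outputs. The heading-based
straight-walking rule uses stance-phase headings (the stance-to-stance
change), one of several defensible readings. The 52-entry catalog fills the
stated four-domain structure around the dozen named measures; other
reconstructions of the unnamed entries are possible. Separated logistic fits
are reported at the iteration cap rather than penalized; with very small
cohorts the Firth-style alternative (not implemented) would shrink the
coefficients but not change the AUC ranking materially, since ranking uses
the linear predictor's order only.
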