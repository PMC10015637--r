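# dailygait

Daily-life gait and turning analysis from wearable inertial sensors, with
best-subsets fall-risk model selection — an R implementation of the analysis
chain used to ask whether a week of passive gait monitoring in people with
Parkinson's disease predicts future falls better than fall history alone.

Three sensors (one per foot, one lumbar; tri-axial accelerometer + gyroscope
at 128 Hz, worn ≥ 8 h/day for ~7 days) yield raw streams. The pipeline:

1. **Gait events** — foot pitch from strapdown gyro integration with
   zero-velocity (foot-flat) drift anchoring; swing detection from
   pitch-velocity peaks over an adaptive threshold; steps chained into gait
   bouts when consecutive steps are less than 2.5 s apart, bouts kept if
   ≥ 3 s and ≥ 3 steps; strides segmented heel-strike to heel-strike.
2. **Turns** — lumbar yaw rate about the gravity axis, low-passed at 1.5 Hz;
   every excursion whose integrated amplitude exceeds 40° within 0.5–10 s is
   a turn (angle, duration, peak velocity, steps in turn).
3. **Straight walking** — strides whose heading changes ≤ 20° and which do
   not overlap a detected turn.
4. **Measures** — a subject-week reduces to 52 measures in four domains
   (Lower Body, Lower Trunk, Turning, Variability): means and
   stride-to-stride standard deviations of stride quantities pooled over all
   straight strides of the week, plus turning statistics and activity rates.
5. **Fall-risk screen** — with future-faller labels from a 12-month falls
   log, every 2-, 3- and 4-measure subset is fitted by logistic regression;
   the 15 best models per size by `BIC = −2·logL + p·log n` are retained
   (45 models), scored by the empirical AUC
   `(concordant + ½·ties) / (n₁·n₀)` with a stratified-bootstrap 95%
   interval, and the top 10 by AUC are ranked together with how often each
   measure is selected.

A two-tier synthetic-data module — ground-truth event timelines plus a
physics-consistent signal renderer — generates week-long cohorts with known
stride/turn parameters, group effect sizes and fall outcomes, so every stage
is testable without clinical recordings.

## Worked example

Simulate a 17 + 17 cohort (two monitoring days keep the example quick),
reduce each subject's ground-truth events to the measure catalog, and screen
measure combinations for discriminating future fallers:

```r
library(dailygait)

spec   <- cohort_spec(n_days = 2)
cohort <- generate_cohort(spec, seed = 42)
cohort
#> Synthetic cohort: 34 subjects (17 fallers, 17 non-fallers by history)
#>   future fallers: 23, recurrent: 10

measures <- cohort_measures(cohort)
screen <- best_subsets(
  measures[, c("pitch_midswing_mean", "toe_out_sd", "turn_peak_velocity_mean",
               "stride_time_mean", "cadence_sd", "gait_speed_mean",
               "trunk_trans_rom_mean", "turn_angle_mean",
               "foot_strike_angle_sd", "double_support_pct_mean")],
  cohort$labels$future_faller, seed = 42)
screen
#> Best-subsets logistic screen of gait measures
#>   subjects: 34 (0 dropped for missingness), measures: 10
#>   retained 45 models (sizes 2, 3, 4, top 15 per size by BIC)
#>   top 10 by empirical AUC:
#>    1. AUC 1.000 (1.00-1.00)  BIC  14.11  pitch_midswing_mean + turn_peak_velocity_mean + trunk_trans_rom_mean  [separated]
#>    2. AUC 1.000 (1.00-1.00)  BIC  17.63  pitch_midswing_mean + toe_out_sd + turn_peak_velocity_mean + gait_speed_mean  [separated]
#>    ...

empirical_auc(as.numeric(cohort$labels$past_faller),
              cohort$labels$future_faller)
#> [1] 0.8663004
mean(measures$strides_per_hour)
#> [1] 154.0439
```

The screen reads: 45 candidate models survived BIC screening, the ranked
models combine low mid-swing foot pitch, low peak turn velocity and high
toe-out variability — the measures the generator planted as group effects —
and each model's AUC comes with its bootstrap interval. In this clean
synthetic cohort the planted effects are strong enough that top models
separate the groups perfectly (AUC 1.0, flagged `[separated]`); real
free-living cohorts sit lower. Fall history alone scores well below the
gait-measure models. Activity lands near free-living rates (~7.8 bouts,
~155 strides, ~20 turns per wear hour).

The signal route exercises the same stages from raw streams:

```r
truth   <- cohort$subjects[["S01"]]
streams <- render_imu(truth, day = 1)        # left_foot, right_foot, lumbar
events  <- process_day(streams)              # steps, bouts, strides, turns
```

`run_pipeline(config, seed, out)` chains simulate → process → measures →
model and writes `measures.csv`, `strides.csv`, `turns.csv`, `bouts.csv`,
`falls.csv`, `model_report.json` and a human-readable `report.txt`, all
reproducible byte-for-byte from the config hash and seed. A thin command-line
wrapper is installed under `inst/cli/dailygait`
(`dailygait pipeline --config cfg.yaml --seed 7 --out DIR`).

`power_sample_size(0.59, 0.04, 0.54, 0.03)` reproduces the two-sample design
calculation for a turning-variability contrast: 12 subjects per group at
α = 0.05 and 95% power (one-sided).

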