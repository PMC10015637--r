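# Study-design specification for synthetic cohorts.

#' Default generative gait parameters
#'
#' One row per stride/turn/trunk parameter of the generative model, holding the
#' group-level means for non-fallers and fallers, the between-subject SD of the
#' subject mean, the group-level within-subject (stride-to-stride or
#' turn-to-turn) SDs, and the between-subject SD of the within-subject SD
#' (stride-to-stride variability itself differs between people, and is where
#' much of the discriminating signal lives).
#'
#' Units: seconds for times, degrees for angles, degrees/second for angular
#' velocities, metres for lengths, dimensionless for fractions. Defaults place
#' the faller group lower on mid-swing foot pitch and peak turn velocity and
#' higher on toe-out variability, each at roughly 1.5 between-subject SDs.
#'
#' @return data.frame with columns `param`, `mean_nonfaller`, `mean_faller`,
#'   `between_sd`, `within_nonfaller`, `within_faller`, `within_between_sd`.
#' @export
default_gait_params <- function() {
  p <- rbind(
    # param              nf mean  f mean  between  wi nf   wi f   wi between
    c("step_time",          0.525,  0.545,  0.040,  0.035,  0.040,  0.006),
    c("stance_frac",        0.620,  0.630,  0.015,  0.010,  0.012,  0.002),
    c("pitch_toe_off",    -28.0,  -26.5,    2.0,    2.0,    2.2,    0.3),
    c("pitch_midswing",    11.0,    8.0,    2.0,    1.5,    1.6,    0.25),
    c("foot_strike_angle", 18.0,   16.5,    2.0,    2.0,    2.2,    0.3),
    c("toe_out",            7.0,    7.5,    2.0,    2.2,    3.05,   0.55),
    c("stride_length",      1.10,   1.00,   0.10,   0.08,   0.09,   0.012),
    c("elevation",          0.035,  0.030,  0.006,  0.007,  0.008,  0.0012),
    c("lateral_excursion",  0.040,  0.042,  0.008,  0.009,  0.010,  0.0015),
    c("trunk_cor_rom",      6.0,    5.5,    1.5,    1.0,    1.1,    0.15),
    c("trunk_sag_rom",      5.0,    4.6,    1.2,    0.9,    1.0,    0.15),
    c("trunk_trans_rom",    8.0,    7.4,    2.0,    1.2,    1.3,    0.2),
    c("turn_angle",        82.0,   80.0,   10.0,   26.0,   27.0,    3.0),
    c("turn_peak_vel",     95.0,   75.5,   13.0,   20.0,   18.0,    3.0)
  )
  out <- data.frame(param = p[, 1], stringsAsFactors = FALSE)
  num <- apply(p[, -1], 2, as.numeric)
  colnames(num) <- c("mean_nonfaller", "mean_faller", "between_sd",
                     "within_nonfaller", "within_faller", "within_between_sd")
  cbind(out, num)
}

#' Cohort specification for the synthetic-data generator
#'
#' Captures the study design the generator emulates: group sizes, days of
#' monitoring and wear hours per day, daily-life activity structure (gait-bout
#' rate and size, turn rate, turn geometry), the generative gait parameters
#' with their group effects, the fall-outcome model, and the sensor noise
#' model. The defaults correspond to a two-group design of 17 fallers and 17
#' non-fallers monitored for 7 days of at least 8 wear hours each, with
#' activity rates tuned to free-living values of roughly 7.8 gait bouts, 150
#' strides and 20 turns per hour.
#'
#' @param n_fallers,n_nonfallers group sizes.
#' @param n_days monitoring days per subject (>= 1).
#' @param wear_hours_per_day sensor wear per day, hours (> 0).
#' @param bout_rate gait bouts per wear hour.
#' @param bout_steps_meanlog,bout_steps_sdlog,bout_steps_min log-normal
#'   parameters (and lower truncation) for steps per bout.
#' @param turn_rate turns per wear hour.
#' @param turn_within_frac fraction of turns taken while walking (inside a
#'   bout); the rest are standalone turns between bouts.
#' @param turn_min_angle lower truncation of the commanded turn magnitude,
#'   degrees. Kept above the 40 degree detection rule so that commanded and
#'   detectable turns coincide.
#' @param params generative gait parameters, see [default_gait_params()].
#' @param outcome fall-outcome model: list with `mode` (`"logistic"` draws the
#'   future-faller label from a logistic link on the standardized subject-level
#'   latents named in `coefficients`; `"group"` makes the faller group the
#'   future fallers deterministically), `intercept`, `coefficients` (named),
#'   and `recurrent_rate` (Poisson mean of extra falls among future fallers).
#' @param noise sensor noise: list with `accel_sd` (m/s^2 per sample),
#'   `gyro_sd` (deg/s per sample), `gyro_bias_sd` (deg/s, constant per day).
#' @param fs sampling rate, Hz.
#' @param seed integer seed; `generate_cohort()` sets it before drawing.
#' @return object of class `cohort_spec` (a validated list).
#' @export
cohort_spec <- function(n_fallers = 17, n_nonfallers = 17,
                        n_days = 7, wear_hours_per_day = 9.2,
                        bout_rate = 7.8,
                        bout_steps_meanlog = 2.76, bout_steps_sdlog = 0.65,
                        bout_steps_min = 8,
                        turn_rate = 20, turn_within_frac = 0.6,
                        turn_min_angle = 45,
                        params = default_gait_params(),
                        outcome = list(mode = "logistic", intercept = 1.2,
                                       coefficients = c(pitch_midswing = -1.1,
                                                        toe_out_within_sd = 1.1,
                                                        turn_peak_vel = -1.1),
                                       recurrent_rate = 0.9),
                        noise = list(accel_sd = 0.03, gyro_sd = 0.5,
                                     gyro_bias_sd = 0.05),
                        fs = 128, seed = NULL) {
  spec <- list(n_fallers = n_fallers, n_nonfallers = n_nonfallers,
               n_days = n_days, wear_hours_per_day = wear_hours_per_day,
               bout_rate = bout_rate, bout_steps_meanlog = bout_steps_meanlog,
               bout_steps_sdlog = bout_steps_sdlog,
               bout_steps_min = bout_steps_min,
               turn_rate = turn_rate, turn_within_frac = turn_within_frac,
               turn_min_angle = turn_min_angle,
               params = params, outcome = outcome, noise = noise,
               fs = fs, seed = seed)
  validate_cohort_spec(spec)
  class(spec) <- "cohort_spec"
  spec
}

validate_cohort_spec <- function(spec) {
  stopifnot(spec$n_fallers >= 0, spec$n_nonfallers >= 0)
  if (spec$n_days < 1) stop("n_days must be >= 1")
  if (spec$wear_hours_per_day <= 0) stop("wear_hours_per_day must be > 0")
  if (spec$bout_rate < 0 || spec$turn_rate < 0) stop("rates must be >= 0")
  p <- spec$params
  need <- c("param", "mean_nonfaller", "mean_faller", "between_sd",
            "within_nonfaller", "within_faller", "within_between_sd")
  if (!all(need %in% names(p))) stop("params is missing required columns")
  sds <- as.matrix(p[, c("between_sd", "within_nonfaller", "within_faller",
                         "within_between_sd")])
  if (any(sds < 0)) stop("all SDs must be >= 0")
  if (any(!vapply(spec$noise, function(v) v >= 0, logical(1))))
    stop("noise parameters must be >= 0")
  invisible(spec)
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("Synthetic cohort specification\n")
  cat(sprintf("  %d fallers + %d non-fallers, %g days x %g wear h/day at %g Hz\n",
              x$n_fallers, x$n_nonfallers, x$n_days, x$wear_hours_per_day, x$fs))
  cat(sprintf("  activity: %.1f bouts/h, %.1f turns/h (%.0f%% while walking)\n",
              x$bout_rate, x$turn_rate, 100 * x$turn_within_frac))
  cat(sprintf("  %d generative parameters; outcome mode '%s'\n",
              nrow(x$params), x$outcome$mode))
  invisible(x)
}
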