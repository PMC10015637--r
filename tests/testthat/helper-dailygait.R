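# Shared fixtures and independent reference implementations.

# subject-level parameter lists from the default table
default_latent <- function(group = "nonfaller", ...) {
  p <- default_gait_params()
  col <- if (group == "faller") "mean_faller" else "mean_nonfaller"
  out <- as.list(stats::setNames(p[[col]], p$param))
  utils::modifyList(out, list(...))
}

default_within <- function(group = "nonfaller", ...) {
  p <- default_gait_params()
  col <- if (group == "faller") "within_faller" else "within_nonfaller"
  out <- as.list(stats::setNames(p[[col]], p$param))
  utils::modifyList(out, list(...))
}

# a short, nearly deterministic subject-day for rendering tests
tiny_truth <- function(seed = 1, wear_h = 0.3, turn_rate = 20, bout_rate = 7.8,
                       latent = default_latent(), within = default_within(),
                       ...) {
  spec <- cohort_spec(n_days = 1, wear_hours_per_day = wear_h,
                      turn_rate = turn_rate, bout_rate = bout_rate, ...)
  generate_subject_week(latent, within, spec, seed = seed)
}

# lumbar stream with a commanded trapezoidal yaw excursion (upright trunk)
trapezoid_lumbar <- function(angle, peak, fs = 128, pre = 3, post = 3,
                             ramp_frac = 0.3) {
  dur <- abs(angle) / ((1 - ramp_frac) * peak)
  n_pre <- as.integer(pre * fs); n_post <- as.integer(post * fs)
  n_t <- as.integer(ceiling(dur * fs))
  u <- (seq_len(n_t) - 0.5) / (dur * fs)
  shape <- pmin(u / ramp_frac, 1, (1 - u) / ramp_frac) / (1 - ramp_frac)
  gz <- c(numeric(n_pre), sign(angle) * abs(angle) / dur * shape, numeric(n_post))
  n <- length(gz)
  imu_stream("lumbar", (seq_len(n) - 1) / fs,
             cbind(0, 0, rep(9.80665, n)), cbind(0, 0, gz), fs)
}

# brute-force reference for the bout rules: chain merged step times with the
# gap rule, then apply the duration and count filters, one step at a time
bouts_reference <- function(times, gap = 2.5, min_dur = 3, min_steps = 3) {
  ts <- sort(times)
  if (!length(ts)) return(list())
  groups <- list(ts[1])
  for (t in ts[-1]) {
    last <- groups[[length(groups)]]
    if (t - last[length(last)] < gap)
      groups[[length(groups)]] <- c(last, t)
    else groups[[length(groups) + 1L]] <- t
  }
  Filter(function(g) (max(g) - min(g)) >= min_dur && length(g) >= min_steps,
         groups)
}

# independent best-subsets reference built on glm
best_subsets_reference <- function(x, y, sizes, top_per_size) {
  x <- as.data.frame(x)
  xs <- as.data.frame(scale(x))
  out <- list()
  for (k in sizes) {
    combos <- utils::combn(names(x), k, simplify = FALSE)
    res <- lapply(combos, function(cs) {
      fit <- suppressWarnings(stats::glm(y ~ ., family = stats::binomial(),
                                         data = cbind(xs[cs], y = y)))
      data.frame(measures = paste(cs, collapse = " + "),
                 bic = -2 * as.numeric(stats::logLik(fit)) + (k + 1) * log(length(y)),
                 stringsAsFactors = FALSE)
    })
    res <- do.call(rbind, res)
    res <- res[order(res$bic, res$measures), ]
    out[[as.character(k)]] <- utils::head(res$measures, top_per_size)
  }
  out
}

# match detected to truth events within a tolerance; returns recall/precision
event_match <- function(truth_times, det_times, tol = 0.1) {
  recall <- if (!length(truth_times)) NA_real_ else
    mean(vapply(truth_times, function(t) any(abs(det_times - t) <= tol),
                logical(1)))
  precision <- if (!length(det_times)) NA_real_ else
    mean(vapply(det_times, function(t) any(abs(truth_times - t) <= tol),
                logical(1)))
  list(recall = recall, precision = precision)
}

# measure table + labels for a planted-effect cohort (ground-truth route):
# exactly three measures carry a 1.5-between-SD group effect (mid-swing pitch
# and peak turn velocity through their means, toe-out through its
# stride-to-stride SD); every other parameter is identical across groups
planted_params <- function(d = 1.5) {
  p <- default_gait_params()
  p$mean_faller <- p$mean_nonfaller
  p$within_faller <- p$within_nonfaller
  i <- p$param == "pitch_midswing"
  p$mean_faller[i] <- p$mean_nonfaller[i] - d * p$between_sd[i]
  i <- p$param == "turn_peak_vel"
  p$mean_faller[i] <- p$mean_nonfaller[i] - d * p$between_sd[i]
  i <- p$param == "toe_out"
  p$within_faller[i] <- p$within_nonfaller[i] + d * p$within_between_sd[i]
  p
}

planted_cohort_measures <- function(seed, n_days = 2) {
  spec <- cohort_spec(n_days = n_days, params = planted_params(),
                      outcome = list(mode = "group", recurrent_rate = 0.9))
  co <- generate_cohort(spec, seed = seed)
  mm <- cohort_measures(co)
  list(measures = mm, y = co$labels$future_faller, labels = co$labels)
}

planted_measures <- c("pitch_midswing_mean", "toe_out_sd", "turn_peak_velocity_mean")
candidate_measures <- c(planted_measures,
                        "stride_time_mean", "cadence_sd", "stance_pct_mean",
                        "gait_speed_mean", "trunk_trans_rom_mean",
                        "turn_angle_mean", "elevation_mean",
                        "foot_strike_angle_sd", "double_support_pct_mean")

# a static foot-site stream at a fixed pitch
static_foot_stream <- function(pitch_deg, n_s = 3, fs = 128, noise = 0) {
  n <- n_s * fs
  g <- 9.80665
  th <- pitch_deg * pi / 180
  accel <- cbind(rep(-g * sin(th), n), 0, rep(g * cos(th), n))
  gyro <- matrix(rnorm(3 * n, 0, noise), n, 3)
  imu_stream("left_foot", (seq_len(n) - 1) / fs, accel, gyro, fs)
}

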