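# Stream-level processing: one wear day / one subject-week through the full
# detection pipeline.

# Per-stride lower-trunk kinematics from the lumbar stream: coronal (roll),
# sagittal (pitch) and transverse (yaw) range of motion and peak angular
# velocity between the stride's heel-strikes. Roll and pitch come from a
# complementary filter (low-passed accelerometer inclination + high-passed
# gyro integral); Euler rates are recovered from the body rates with the
# estimated angles, integrated per stride and linearly detrended.
attach_trunk_measures <- function(strides, lumbar, config = dailygait_config()) {
  cols <- c("trunk_cor_rom", "trunk_sag_rom", "trunk_trans_rom",
            "trunk_cor_peak_vel", "trunk_sag_peak_vel", "trunk_trans_peak_vel")
  if (is.null(strides) || !nrow(strides)) return(strides)
  for (cc in cols) strides[[cc]] <- NA_real_
  if (is.null(lumbar)) return(strides)
  fs <- lumbar$fs
  dt <- 1 / fs
  a <- lumbar$accel; g <- lumbar$gyro
  th_acc <- atan2(-a[, 1], sqrt(a[, 2]^2 + a[, 3]^2)) / d2r
  ph_acc <- atan2(a[, 2], a[, 3]) / d2r
  th_g <- cumtrapz_dt(g[, 2], dt)
  ph_g <- cumtrapz_dt(g[, 1], dt)
  fc <- 0.3
  th <- lowpass(th_acc, fs, fc) + th_g - lowpass(th_g, fs, fc)
  ph <- lowpass(ph_acc, fs, fc) + ph_g - lowpass(ph_g, fs, fc)
  sph <- sin(ph * d2r); cph <- cos(ph * d2r); tth <- tan(pmin(pmax(th, -80), 80) * d2r)
  cth <- cos(th * d2r)
  rate_cor <- g[, 1] + (g[, 2] * sph + g[, 3] * cph) * tth
  rate_sag <- g[, 2] * cph - g[, 3] * sph
  rate_trans <- (g[, 2] * sph + g[, 3] * cph) / cth
  sm <- function(x) lowpass(x, fs, config$rate_lp_hz)
  rs_cor <- sm(rate_cor); rs_sag <- sm(rate_sag); rs_trans <- sm(rate_trans)
  int_cor <- cumtrapz_dt(rate_cor, dt)
  int_sag <- cumtrapz_dt(rate_sag, dt)
  int_trans <- cumtrapz_dt(rate_trans, dt)

  i0 <- pmin(pmax(grid_idx(lumbar, strides$t_start) + 1L, 1L), length(lumbar$time))
  i1 <- pmin(pmax(grid_idx(lumbar, strides$t_end), 1L), length(lumbar$time))
  rng <- function(intg, ii) {
    y <- intg[ii]
    m <- length(y)
    y <- y - (y[1] + (y[m] - y[1]) * (seq_len(m) - 1) / (m - 1))
    max(y) - min(y)
  }
  for (k in seq_len(nrow(strides))) {
    if (i1[k] - i0[k] < 4) next
    ii <- i0[k]:i1[k]
    strides$trunk_cor_rom[k] <- rng(int_cor, ii)
    strides$trunk_sag_rom[k] <- rng(int_sag, ii)
    strides$trunk_trans_rom[k] <- rng(int_trans, ii)
    strides$trunk_cor_peak_vel[k] <- max(abs(rs_cor[ii]))
    strides$trunk_sag_peak_vel[k] <- max(abs(rs_sag[ii]))
    strides$trunk_trans_peak_vel[k] <- max(abs(rs_trans[ii]))
  }
  strides
}

#' Run the detection pipeline on one wear day of streams
#'
#' Chains foot-angle estimation, step detection on both feet, bout assembly
#' with the inter-step gap rule and the bout filter, stride segmentation,
#' lumbar turn detection, straight-walking selection and per-stride trunk
#' kinematics.
#'
#' @param streams named list with `left_foot`, `right_foot`, `lumbar`
#'   [imu_stream()]s (as produced by [render_imu()] or read from disk).
#' @param config a [dailygait_config()].
#' @return list with `steps`, `bouts`, `strides`, `turns` data.frames.
#' @export
process_day <- function(streams, config = dailygait_config()) {
  stopifnot(all(c("left_foot", "right_foot", "lumbar") %in% names(streams)))
  angles <- list(left = estimate_foot_angles(streams$left_foot, config),
                 right = estimate_foot_angles(streams$right_foot, config))
  steps <- rbind(detect_steps(angles$left, config),
                 detect_steps(angles$right, config))
  steps <- steps[order(steps$t_hs), ]
  rownames(steps) <- NULL

  turns <- detect_turns(streams$lumbar, config)
  turns <- characterize_turns(turns, steps)

  bouts <- assemble_bouts(steps$t_hs, config)
  strides <- NULL
  if (nrow(bouts)) {
    traj <- list(left = foot_trajectory(streams$left_foot, angles$left),
                 right = foot_trajectory(streams$right_foot, angles$right))
    sl <- lapply(seq_len(nrow(bouts)), function(b) {
      s <- segment_strides(bouts[b, ], steps, angles, traj, config)
      if (!is.null(s)) s$bout <- bouts$bout[b]
      s
    })
    sl <- Filter(Negate(is.null), sl)
    if (length(sl)) strides <- as.data.frame(data.table::rbindlist(sl))
  }
  strides <- flag_straight_strides(strides, turns, config)
  strides <- attach_trunk_measures(strides, streams$lumbar, config)
  list(steps = steps, bouts = bouts, strides = strides, turns = turns)
}

#' Render and process a synthetic subject through the full pipeline
#'
#' Renders each wear day of a ground-truth timeline to IMU streams, runs
#' [process_day()] on them, pools the events over the week and reduces them to
#' the measure catalog. This is the signal-level (tolerance-based) route; the
#' ground-truth event tables in the `subject_truth` are the exact route.
#'
#' @param truth a `subject_truth`.
#' @param noise noise setting passed to [render_imu()].
#' @param config a [dailygait_config()].
#' @param days which days to process (default: all).
#' @param catalog a [measure_catalog()].
#' @return list with pooled `steps`, `bouts`, `strides`, `turns` (all carrying
#'   `day`), and `measures` (one-row data.frame).
#' @export
process_subject <- function(truth, noise = TRUE, config = dailygait_config(),
                            days = seq_len(truth$n_days),
                            catalog = measure_catalog()) {
  acc <- list(steps = list(), bouts = list(), strides = list(), turns = list())
  for (d in days) {
    streams <- render_imu(truth, day = d, noise = noise)
    res <- process_day(streams, config)
    for (nm in names(acc)) {
      x <- res[[nm]]
      if (!is.null(x) && nrow(x)) { x$day <- d; acc[[nm]][[length(acc[[nm]]) + 1L]] <- x }
    }
  }
  bind <- function(lst) if (length(lst)) as.data.frame(data.table::rbindlist(lst)) else NULL
  steps <- bind(acc$steps); bouts <- bind(acc$bouts)
  strides <- bind(acc$strides); turns <- bind(acc$turns)
  wear_h <- length(days) * truth$days$wear_s[1] / 3600
  measures <- compute_subject_measures(strides, turns, bouts, wear_h, catalog)
  list(steps = steps, bouts = bouts, strides = strides, turns = turns,
       measures = measures)
}
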