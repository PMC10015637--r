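# Turn detection and characterization from the lumbar sensor.

# zero-phase Butterworth low-pass; falls back to the identity for streams too
# short to filter
lowpass <- function(x, fs, hz) {
  if (length(x) < 24 || hz >= fs / 2) return(x)
  bf <- signal::butter(2, hz / (fs / 2), type = "low")
  as.numeric(signal::filtfilt(bf, x))
}

# yaw rate about the gravity axis: gravity direction from low-passed
# accelerometer, re-estimated continuously
gravity_yaw_rate <- function(stream, config = dailygait_config()) {
  a_lp <- apply(stream$accel, 2, lowpass, fs = stream$fs, hz = config$gravity_lp_hz)
  nrm <- sqrt(rowSums(a_lp^2))
  nrm[nrm < 1e-6] <- 1
  g_hat <- a_lp / nrm
  rowSums(stream$gyro * g_hat)
}

#' Detect turns from the lumbar sensor
#'
#' The yaw rate (gyro component about the gravity axis, gravity estimated
#' from the low-passed accelerometer) is low-pass filtered at 1.5 Hz;
#' candidate turns start and end where the magnitude crosses 5 deg/s around
#' an excursion exceeding 15 deg/s; same-direction candidates separated by
#' less than 0.1 s are merged; candidates are kept as turns only if the
#' integrated yaw rate exceeds 40 degrees in magnitude and the duration lies
#' in [0.5, 10] s. The turn angle is the time-integral of the (unfiltered)
#' yaw rate over the event and the peak velocity its maximum magnitude.
#'
#' @param stream an [imu_stream()] from the lumbar site.
#' @param config a [dailygait_config()].
#' @return data.frame with one row per turn: `t_start`, `t_end`, `duration`,
#'   `angle` (signed, deg), `magnitude`, `peak_velocity`, `mean_velocity`,
#'   `direction` (`"left"` = counter-clockwise).
#' @export
detect_turns <- function(stream, config = dailygait_config()) {
  if (!inherits(stream, "imu_stream")) stop("stream must be an imu_stream")
  if (stream$site != "lumbar") stop("detect_turns needs the lumbar stream")
  empty <- data.frame(t_start = numeric(0), t_end = numeric(0),
                      duration = numeric(0), angle = numeric(0),
                      magnitude = numeric(0), peak_velocity = numeric(0),
                      mean_velocity = numeric(0), direction = character(0),
                      stringsAsFactors = FALSE)
  n <- length(stream$time)
  if (n < 8) return(empty)
  fs <- stream$fs
  yr_raw <- gravity_yaw_rate(stream, config)
  yr <- lowpass(yr_raw, fs, config$turn_lp_hz)

  cands <- list()
  for (sgn in c(1, -1)) {
    above <- sgn * yr > config$turn_edge_rate
    runs <- logical_runs(above)
    if (!nrow(runs)) next
    for (k in seq_len(nrow(runs))) {
      i <- runs$start[k]:runs$end[k]
      if (max(sgn * yr[i]) > config$turn_excursion)
        cands[[length(cands) + 1L]] <- list(start = runs$start[k],
                                            end = runs$end[k], sgn = sgn)
    }
  }
  if (!length(cands)) return(empty)
  cd <- do.call(rbind, lapply(cands, as.data.frame))
  cd <- cd[order(cd$start), ]
  # merge same-direction candidates separated by < turn_merge_gap
  merged <- list(cd[1, ])
  if (nrow(cd) > 1) for (k in 2:nrow(cd)) {
    last <- merged[[length(merged)]]
    gap <- (cd$start[k] - last$end) / fs
    if (cd$sgn[k] == last$sgn && gap < config$turn_merge_gap) {
      last$end <- cd$end[k]
      merged[[length(merged)]] <- last
    } else merged[[length(merged) + 1L]] <- cd[k, ]
  }

  rows <- list()
  dt <- 1 / fs
  for (m in merged) {
    # refine the boundaries on the unfiltered yaw rate: from the excursion
    # peak, walk outward to the edge-rate crossings (the low-pass smears the
    # flanks of sharp turns)
    i <- m$start:m$end
    p <- i[which.max(m$sgn * yr_raw[i])]
    below <- which(m$sgn * yr_raw <= config$turn_edge_rate)
    j <- findInterval(p, below)
    i0 <- if (j >= 1) below[j] + 1L else 1L
    i1 <- if (j < length(below)) below[j + 1] - 1L else n
    # sub-sample crossing times at the edge rate
    edge <- m$sgn * config$turn_edge_rate
    t0 <- stream$time[i0]
    if (i0 > 1) {
      d <- yr_raw[i0] - yr_raw[i0 - 1]
      if (abs(d) > 1e-12)
        t0 <- stream$time[i0 - 1] + (edge - yr_raw[i0 - 1]) / d * dt
    }
    t1 <- stream$time[i1]
    if (i1 < n) {
      d <- yr_raw[i1 + 1] - yr_raw[i1]
      if (abs(d) > 1e-12)
        t1 <- stream$time[i1] + (edge - yr_raw[i1]) / d * dt
    }
    dur <- t1 - t0
    if (dur < config$turn_min_duration || dur > config$turn_max_duration) next
    ii <- i0:i1
    if (length(ii) < 2) next
    ang <- sum((yr_raw[ii][-1] + yr_raw[ii][-length(ii)]) / 2) * dt
    if (abs(ang) <= config$turn_min_angle) next
    rows[[length(rows) + 1L]] <- list(
      t_start = t0, t_end = t1,
      duration = dur, angle = ang, magnitude = abs(ang),
      peak_velocity = max(abs(yr_raw[ii])),
      mean_velocity = abs(ang) / dur,
      direction = if (ang > 0) "left" else "right")
  }
  if (!length(rows)) return(empty)
  out <- as.data.frame(data.table::rbindlist(rows))
  stopifnot(all(out$magnitude > config$turn_min_angle))
  out
}

#' Count the steps taken inside each turn
#'
#' A step belongs to a turn when its swing-peak time lies inside the turn
#' interval.
#'
#' @param turns output of [detect_turns()].
#' @param steps merged step table with `t_peak`.
#' @return `turns` with an `n_steps_in` column.
#' @export
characterize_turns <- function(turns, steps) {
  if (is.null(turns) || !nrow(turns)) return(turns)
  pk <- if (!is.null(steps) && nrow(steps)) steps$t_peak else numeric(0)
  turns$n_steps_in <- vapply(seq_len(nrow(turns)), function(i)
    sum(pk >= turns$t_start[i] & pk <= turns$t_end[i]), numeric(1))
  turns
}
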