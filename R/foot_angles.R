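# Foot orientation and trajectory recovery from raw inertial streams.

#' Pipeline configuration defaults
#'
#' All tunable constants of the detection pipeline in one place. The
#' scientific rules (2.5 s inter-step gap, 3 s / 3 step bout filter, 20 deg
#' straight-walking rule, 40 deg turn amplitude) sit alongside the
#' implementation constants of the detectors (thresholds, windows, merge
#' gaps), each overridable.
#'
#' @param ... overrides of the defaults listed below.
#' @return named list of configuration values.
#' @export
dailygait_config <- function(...) {
  cfg <- list(
    fs = 128,                 # Hz nominal sampling rate
    step_gap_max = 2.5,       # s: steps closer than this chain into a bout
    bout_min_duration = 3,    # s: first-step-to-last-step bout filter
    bout_min_steps = 3,       # minimum steps per bout
    straight_max_heading = 20,# deg heading change per stride for straight walk
    turn_min_angle = 40,      # deg amplitude rule for turns
    turn_excursion = 15,      # deg/s: a candidate must exceed this yaw rate
    turn_edge_rate = 5,       # deg/s: candidate start/end crossings
    turn_merge_gap = 0.1,     # s: same-direction candidates closer are merged
    turn_min_duration = 0.5,  # s
    turn_max_duration = 10,   # s
    turn_lp_hz = 1.5,         # Hz low-pass for the yaw-rate detection signal
    gravity_lp_hz = 0.5,      # Hz low-pass for the gravity-axis estimate
    step_thresh_frac = 0.2,   # fraction of the robust pitch-velocity amplitude
    step_thresh_quantile = 0.9,
    step_thresh_floor = 30,   # deg/s
    step_thresh_window = 10,  # s blocks for the adaptive threshold
    step_min_separation = 0.25, # s between swing peaks
    flat_gyro_thresh = 8,     # deg/s gyro magnitude bound for foot-flat
    flat_min_duration = 0.05, # s minimal foot-flat interval
    rate_lp_hz = 6,           # Hz smoothing of rate signals for peak reads
    variability = "sd"        # or "cv"
  )
  ov <- list(...)
  unknown <- setdiff(names(ov), names(cfg))
  if (length(unknown)) stop("unknown config fields: ", paste(unknown, collapse = ", "))
  utils::modifyList(cfg, ov)
}

# cumulative trapezoid integral with step dt, starting at 0
cumtrapz_dt <- function(x, dt) {
  n <- length(x)
  if (n < 2) return(numeric(n))
  c(0, cumsum((x[-1] + x[-n]) / 2)) * dt
}

# runs of TRUE at least min_len long; returns data.frame(start, end) indices
logical_runs <- function(x, min_len = 1L) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_len
  data.frame(start = starts[keep], end = ends[keep])
}

#' Estimate foot orientation angles from a foot-worn IMU
#'
#' Strapdown integration of the pitch gyro with zero-velocity drift
#' correction: foot-flat intervals (gyro magnitude below a threshold for at
#' least 0.05 s) anchor the pitch angle to the accelerometer-derived
#' inclination, and integration runs between anchors. Heading is integrated
#' from the gravity-axis gyro component; it carries slow drift, which is
#' acceptable because heading is only used for within-stride changes and for
#' toe-out relative to the bout's travel direction. Foot roll is assumed
#' negligible (flat-mounted sensor), so pitch rate is read directly from the
#' y gyro.
#'
#' @param stream an [imu_stream()] from a foot site.
#' @param config a [dailygait_config()].
#' @return object of class `foot_angles`: list with `time`, `pitch` (deg),
#'   `heading` (deg, unwrapped, starting at 0), `pitch_rate` (deg/s),
#'   `stance` (logical foot-flat flag per sample), `flat_runs`, `fs`, `side`.
#' @export
estimate_foot_angles <- function(stream, config = dailygait_config()) {
  if (!inherits(stream, "imu_stream")) stop("stream must be an imu_stream")
  if (stream$site == "lumbar") stop("estimate_foot_angles needs a foot site")
  fs <- stream$fs
  n <- length(stream$time)
  empty <- list(time = numeric(0), pitch = numeric(0), heading = numeric(0),
                pitch_rate = numeric(0), stance = logical(0),
                flat_runs = data.frame(start = integer(0), end = integer(0)),
                fs = fs, side = sub("_foot", "", stream$site))
  class(empty) <- "foot_angles"
  if (n < fs) return(empty)

  g <- stream$gyro
  a <- stream$accel
  dt <- 1 / fs
  gm <- sqrt(rowSums(g^2))
  flat <- gm < config$flat_gyro_thresh
  runs <- logical_runs(flat, min_len = max(2L, as.integer(config$flat_min_duration * fs)))

  # pitch: integrate gy, re-anchoring at each foot-flat midpoint to the
  # accelerometer inclination averaged over the flat run
  integ <- cumtrapz_dt(g[, 2], dt)
  pitch <- integ
  if (nrow(runs)) {
    mids <- as.integer((runs$start + runs$end) / 2)
    th_acc <- vapply(seq_len(nrow(runs)), function(k) {
      i <- runs$start[k]:runs$end[k]
      atan2(-mean(a[i, 1]), sqrt(mean(a[i, 2])^2 + mean(a[i, 3])^2)) / d2r
    }, numeric(1))
    grp <- findInterval(seq_len(n), mids)
    off <- c(0, th_acc - integ[mids])   # group 0: before the first anchor
    # anchor the pre-first-anchor segment so it ends at the first anchor value
    off[1] <- off[2]
    pitch <- integ + off[grp + 1L]
  }
  heading <- cumtrapz_dt(g[, 3] / pmax(cos(pitch * d2r), 0.2), dt)

  out <- list(time = stream$time, pitch = pitch, heading = heading,
              pitch_rate = g[, 2], stance = flat, flat_runs = runs,
              fs = fs, side = sub("_foot", "", stream$site))
  class(out) <- "foot_angles"
  out
}

#' @export
print.foot_angles <- function(x, ...) {
  cat(sprintf("Foot angle series [%s]: %d samples, %d foot-flat intervals\n",
              x$side, length(x$time), nrow(x$flat_runs)))
  invisible(x)
}

# ZUPT-aided double integration of foot acceleration: world-frame velocity is
# zeroed at every foot-flat anchor with linear drift removal in between, then
# integrated to position per inter-anchor segment. Returns per-segment swing
# geometry keyed by the anchor pair flanking each swing.
foot_trajectory <- function(stream, angles) {
  fs <- stream$fs
  n <- length(stream$time)
  runs <- angles$flat_runs
  if (nrow(runs) < 2) {
    return(data.frame(t0 = numeric(0), t1 = numeric(0), length = numeric(0),
                      elevation = numeric(0), lateral = numeric(0),
                      dir = numeric(0)))
  }
  dt <- 1 / fs
  th <- angles$pitch * d2r
  ps <- angles$heading * d2r
  cth <- cos(th); sth <- sin(th); cps <- cos(ps); sps <- sin(ps)
  ax <- stream$accel[, 1]; ay <- stream$accel[, 2]; az <- stream$accel[, 3]
  # world = Rz(psi) Ry(theta) body   (roll assumed zero)
  u1 <- cth * ax + sth * az
  u3 <- -sth * ax + cth * az - GRAVITY
  aX <- cps * u1 - sps * ay
  aY <- sps * u1 + cps * ay
  aZ <- u3

  # integrate only over the movement window between consecutive foot-flat
  # intervals (long idle stretches would let velocity-drift corrections leak
  # into the displacement direction)
  lo <- pmax(runs$end - 2L, 1L)
  hi <- pmin(runs$start + 2L, n)
  K <- nrow(runs)
  out <- data.frame(t0 = numeric(K - 1), t1 = numeric(K - 1),
                    length = numeric(K - 1), elevation = numeric(K - 1),
                    lateral = numeric(K - 1), dir = numeric(K - 1))
  for (k in seq_len(K - 1)) {
    i <- lo[k]:hi[k + 1]
    m <- length(i)
    if (m < 3) { out[k, ] <- c(stream$time[lo[k]], stream$time[hi[k + 1]], 0, 0, 0, 0); next }
    vx <- cumtrapz_dt(aX[i], dt); vy <- cumtrapz_dt(aY[i], dt)
    vz <- cumtrapz_dt(aZ[i], dt)
    w <- (seq_len(m) - 1) / (m - 1)       # linear drift correction to v=0 at both ends
    vx <- vx - w * vx[m]; vy <- vy - w * vy[m]; vz <- vz - w * vz[m]
    px <- cumtrapz_dt(vx, dt); py <- cumtrapz_dt(vy, dt); pz <- cumtrapz_dt(vz, dt)
    dx <- px[m]; dy <- py[m]
    L <- sqrt(dx^2 + dy^2)
    # lateral: max deviation from the straight line between the anchors
    lat <- if (L > 1e-6) max(abs(px * dy - py * dx) / L) else 0
    out$t0[k] <- stream$time[lo[k]]
    out$t1[k] <- stream$time[hi[k + 1]]
    out$length[k] <- L
    out$elevation[k] <- max(pz - w * pz[m])
    out$lateral[k] <- lat
    out$dir[k] <- atan2(dy, dx) / d2r
  }
  out
}
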