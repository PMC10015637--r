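# Signal-level renderer: ground-truth timelines -> three-site IMU streams.
#
# Orientation convention (both feet and lumbar): world frame z-up, yaw psi
# about world z (deg, CCW positive = left), pitch theta about the intermediate
# y axis (deg, positive = toe/trunk up), roll phi about body x. The rotation
# world<-body is Rz(psi) Ry(theta) Rx(phi); with this convention the body
# angular rates are
#   p = phi' - psi' sin(theta)
#   q = theta' cos(phi) + psi' cos(theta) sin(phi)
#   r = -theta' sin(phi) + psi' cos(theta) cos(phi)
# and a resting accelerometer reads g * (-sin(theta), cos(theta) sin(phi),
# cos(theta) cos(phi)). Angles are carried in degrees throughout; only the
# trigonometric evaluations convert.

GRAVITY <- 9.80665
LUMBAR_LEAN <- 3       # deg of habitual forward trunk lean
LUMBAR_BOB <- 0.4      # m/s^2 vertical bob amplitude at step frequency
BOUT_ENV_RAMP <- 0.3   # s amplitude ramp of trunk oscillation at bout edges
TURN_SUPP_RAMP <- 0.3  # s transverse-oscillation taper flanking a turn

d2r <- pi / 180

#' Tri-axial IMU stream container
#'
#' @param site one of `"left_foot"`, `"right_foot"`, `"lumbar"`.
#' @param time sample times, seconds, strictly increasing, nominally uniform.
#' @param accel N x 3 accelerometer matrix, m/s^2 (specific force).
#' @param gyro N x 3 gyroscope matrix, deg/s.
#' @param fs nominal sampling rate, Hz.
#' @return object of class `imu_stream`.
#' @export
imu_stream <- function(site, time, accel, gyro, fs) {
  site <- match.arg(site, c("left_foot", "right_foot", "lumbar"))
  accel <- as.matrix(accel); gyro <- as.matrix(gyro)
  if (length(time) != nrow(accel) || length(time) != nrow(gyro))
    stop("time, accel and gyro must have matching lengths")
  if (length(time) > 1 && any(diff(time) <= 0))
    stop("sample times must be strictly increasing")
  structure(list(site = site, time = as.numeric(time), accel = accel,
                 gyro = gyro, fs = fs), class = "imu_stream")
}

#' @export
print.imu_stream <- function(x, ...) {
  cat(sprintf("IMU stream [%s]: %d samples at %g Hz (%.1f min)\n",
              x$site, length(x$time), x$fs,
              diff(range(x$time)) / 60))
  invisible(x)
}

# sample indices of [t0, t1) on the grid t_i = (i-1)/fs
seg_idx <- function(t0, t1, fs, n) {
  i0 <- max(1L, as.integer(ceiling(t0 * fs - 1e-9)) + 1L)
  i1 <- min(n, as.integer(ceiling(t1 * fs - 1e-9)))
  if (i1 < i0) integer(0) else i0:i1
}

# half-cosine ease from a to b over duration D: value and rate at offset u
ease_val <- function(u, a, b, D) a + (b - a) * (1 - cos(pi * u / D)) / 2
ease_rate <- function(u, a, b, D) (b - a) * pi / (2 * D) * sin(pi * u / D)

# Two-piece sinusoidal swing bump: the angular velocity rises as
# V sin(pi u / 2 b1) and falls as V cos(pi (u - b1) / 2 b2), so it peaks at
# u = b1 = r D (where the integrated pitch passes exactly th_ms) and meets
# zero with non-zero slope at both ends, making toe-off and heel-strike sharp
# landmarks. V = pi (th_fs - th_to) / (2 D); the area split fixes r.
swing_pitch <- function(u, th_to, th_ms, th_fs, D) {
  r <- (th_ms - th_to) / (th_fs - th_to)
  V <- pi * (th_fs - th_to) / (2 * D)
  b1 <- r * D; b2 <- D - b1
  out <- numeric(length(u))
  i <- u <= b1
  out[i] <- th_to + V * (2 * b1 / pi) * (1 - cos(pi * u[i] / (2 * b1)))
  j <- !i
  out[j] <- th_ms + V * (2 * b2 / pi) * sin(pi * (u[j] - b1) / (2 * b2))
  out
}

swing_pitch_rate <- function(u, th_to, th_ms, th_fs, D) {
  r <- (th_ms - th_to) / (th_fs - th_to)
  V <- pi * (th_fs - th_to) / (2 * D)
  b1 <- r * D; b2 <- D - b1
  out <- numeric(length(u))
  i <- u <= b1
  out[i] <- V * sin(pi * u[i] / (2 * b1))
  j <- !i
  out[j] <- V * cos(pi * (u[j] - b1) / (2 * b2))
  out
}

# travel heading and heading rate (deg, deg/s) on a full day grid
travel_series <- function(t, turns, h0 = 0) {
  n <- length(t)
  h <- rep(h0, n); hdot <- numeric(n)
  if (is.null(turns) || nrow(turns) == 0) return(list(h = h, hdot = hdot))
  o <- order(turns$t_cmd_start)
  s <- turns$t_cmd_start[o]; d <- turns$duration_cmd[o]; a <- turns$angle[o]
  ends <- s + d
  cum <- c(0, cumsum(a))
  h <- h0 + cum[findInterval(t, ends) + 1L]
  fs <- 1 / (t[2] - t[1])
  for (i in seq_along(s)) {
    ii <- seg_idx(s[i], ends[i], fs, n)
    if (!length(ii)) next
    u <- (t[ii] - s[i]) / d[i]
    h[ii] <- cum[i] + a[i] * trap_frac(u)
    hdot[ii] <- a[i] / d[i] * trap_shape(u)
  }
  list(h = h, hdot = hdot)
}

# raised-cosine envelope: 0 before t0, ramps to 1 by t0+ramp, back to 0 at t1
envelope_fill <- function(env, t, t0, t1, ramp, fs) {
  n <- length(t)
  ii <- seg_idx(t0, t1, fs, n)
  if (!length(ii)) return(env)
  env[ii] <- 1
  ri <- seg_idx(t0, min(t0 + ramp, t1), fs, n)
  if (length(ri)) env[ri] <- (1 - cos(pi * (t[ri] - t0) / ramp)) / 2
  ro <- seg_idx(max(t1 - ramp, t0), t1, fs, n)
  if (length(ro)) env[ro] <- pmin(env[ro], (1 - cos(pi * (t1 - t[ro]) / ramp)) / 2)
  env
}

#' Render the IMU streams of one wear day
#'
#' Turns a ground-truth timeline into the three sensor streams: foot pitch is
#' a smooth per-stride trajectory (loading, foot-flat, push-off, swing bump)
#' whose strapdown integral reproduces the commanded toe-off, mid-swing and
#' foot-strike pitch angles; foot heading follows the commanded stance
#' headings (travel direction plus toe-out) and rotates with the body through
#' turns; foot translation renders the commanded stride length, swing
#' elevation and lateral excursion; the lumbar stream renders commanded
#' trapezoidal turn profiles about the gravity axis plus per-stride coronal /
#' sagittal / transverse oscillations with the commanded range of motion.
#' Accelerometers measure gravity in the sensor frame plus movement
#' accelerations plus white noise; gyroscopes get white noise and a constant
#' per-day bias.
#'
#' @param truth a `subject_truth` from [generate_subject_week()].
#' @param day which day to render.
#' @param noise `TRUE` for the noise model carried in the truth object,
#'   `FALSE` for noise-free signals, or a list with `accel_sd`, `gyro_sd`,
#'   `gyro_bias_sd`.
#' @param seed optional seed for the noise draws.
#' @return named list of three [imu_stream()]s: `left_foot`, `right_foot`,
#'   `lumbar`.
#' @export
render_imu <- function(truth, day = 1, noise = TRUE, seed = NULL) {
  if (!inherits(truth, "subject_truth")) stop("truth must be a subject_truth")
  if (!is.null(seed)) set.seed(seed)
  if (isTRUE(noise)) noise <- truth$noise
  if (isFALSE(noise) || is.null(noise))
    noise <- list(accel_sd = 0, gyro_sd = 0, gyro_bias_sd = 0)
  fs <- truth$fs
  dm <- truth$days[truth$days$day == day, ]
  if (nrow(dm) != 1) stop("no such day in the timeline")
  W <- dm$wear_s
  n <- as.integer(round(W * fs))
  t <- (seq_len(n) - 1) / fs

  steps <- sub_day(truth$steps, day)
  turns <- sub_day(truth$turns, day)
  trunk <- sub_day(truth$trunk, day)
  bouts <- sub_day(truth$bouts, day)
  if (!is.null(steps) && nrow(steps) > 0 && any(overlapping_events(steps, turns)))
    stop("timeline has overlapping events")

  tv <- travel_series(t, turns, dm$h0)

  out <- list()
  for (side in c("left", "right")) {
    ch <- render_foot(t, fs, side, steps, tv, trunk, bouts)
    out[[paste0(side, "_foot")]] <- finish_stream(
      paste0(side, "_foot"), t, ch, fs, noise)
  }
  ch <- render_lumbar(t, fs, steps, turns, tv, trunk, bouts)
  out$lumbar <- finish_stream("lumbar", t, ch, fs, noise)
  out
}

sub_day <- function(x, day) {
  if (is.null(x)) return(NULL)
  y <- x[x$day == day, , drop = FALSE]
  if (nrow(y)) y else NULL
}

# standalone turns must not intersect bouts; within-bout turns are aligned to
# step boundaries by construction, so only cross-kind overlap is checked
overlapping_events <- function(steps, turns) {
  if (is.null(turns)) return(FALSE)
  sa <- turns[!turns$within_bout, , drop = FALSE]
  if (!nrow(sa)) return(FALSE)
  vapply(seq_len(nrow(sa)), function(i)
    any(steps$t_hs > sa$t_cmd_start[i] - 1 &
        steps$t_hs < sa$t_cmd_start[i] + sa$duration_cmd[i] + 1), logical(1))
}

# Assemble euler-angle channel series for one foot into body-frame signals.
render_foot <- function(t, fs, side, steps, tv, trunk, bouts) {
  n <- length(t)
  th <- numeric(n); thdot <- numeric(n)          # pitch, deg / deg/s
  psi <- tv$h; psidot <- tv$hdot                 # overwritten below
  anav <- matrix(0, n, 3)
  sgn <- if (side == "left") 1 else -1

  if (is.null(steps))
    return(list(phi = numeric(n), phidot = numeric(n), th = th, thdot = thdot,
                psi = psi, psidot = psidot, anav = anav))

  # ---- pitch and translation, per own landing ----
  for (b in unique(steps$bout)) {
    st <- steps[steps$bout == b, , drop = FALSE]
    mine <- which(st$side == side)
    for (k in seq_along(mine)) {
      m <- mine[k]
      i <- seg_idx(st$t_to[m], st$t_hs[m], fs, n)
      D <- st$swing_dur[m]
      if (length(i)) {
        u <- t[i] - st$t_to[m]
        if (is.na(st$th_to[m])) {            # initial swing from flat foot
          th[i] <- ease_val(u, 0, st$th_fs[m], D)
          thdot[i] <- ease_rate(u, 0, st$th_fs[m], D)
        } else {
          th[i] <- swing_pitch(u, st$th_to[m], st$th_ms[m], st$th_fs[m], D)
          thdot[i] <- swing_pitch_rate(u, st$th_to[m], st$th_ms[m], st$th_fs[m], D)
        }
        hr <- st$h_swing[m] * d2r
        L <- st$swing_len[m]; E <- st$swing_elev[m]; X <- st$swing_lat[m]
        afwd <- 2 * L / D * (pi / D) * sin(2 * pi * u / D)
        alat <- sgn * X * (2 * pi^2 / D^2) * cos(2 * pi * u / D)
        anav[i, 1] <- afwd * cos(hr) - alat * sin(hr)
        anav[i, 2] <- afwd * sin(hr) + alat * cos(hr)
        anav[i, 3] <- E * (2 * pi^2 / D^2) * cos(2 * pi * u / D)
      }
      s_m <- st$stance_dur[m]
      t0 <- st$t_hs[m]
      i <- seg_idx(t0, t0 + 0.25 * s_m, fs, n)
      if (length(i)) {
        u <- t[i] - t0
        th[i] <- ease_val(u, st$th_fs[m], 0, 0.25 * s_m)
        thdot[i] <- ease_rate(u, st$th_fs[m], 0, 0.25 * s_m)
      }
      if (k < length(mine)) {
        nxt <- mine[k + 1]
        po_start <- t0 + 0.70 * s_m
        i <- seg_idx(po_start, t0 + s_m, fs, n)
        if (length(i)) {
          u <- t[i] - po_start
          th[i] <- ease_val(u, 0, st$th_to[nxt], 0.30 * s_m)
          thdot[i] <- ease_rate(u, 0, st$th_to[nxt], 0.30 * s_m)
        }
      }
    }
  }

  # ---- yaw: one continuous chronological pass over this foot's events ----
  prev_end <- 0
  cur_off <- NA_real_   # yaw offset from the travel heading during gaps
  for (b in unique(steps$bout)) {
    st <- steps[steps$bout == b, , drop = FALSE]
    mine <- which(st$side == side)
    if (!length(mine)) next
    sw_start <- st$t_to[mine[1]]
    if (is.na(cur_off)) cur_off <- sgn * st$toe_out[mine[1]]
    i <- seg_idx(prev_end, sw_start, fs, n)
    if (length(i)) { psi[i] <- tv$h[i] + cur_off; psidot[i] <- tv$hdot[i] }
    ig <- seg_idx(sw_start - 2 / fs, sw_start, fs, n)
    h_prev <- (if (length(ig)) tv$h[ig[length(ig)]] else tv$h[1]) + cur_off
    for (k in seq_along(mine)) {
      m <- mine[k]
      D <- st$swing_dur[m]
      i <- seg_idx(st$t_to[m], st$t_hs[m], fs, n)
      if (length(i)) {
        u <- t[i] - st$t_to[m]
        psi[i] <- ease_val(u, h_prev, st$h_stance[m], D) +
          st$wiggle[m] * sin(pi * u / D)
        psidot[i] <- ease_rate(u, h_prev, st$h_stance[m], D) +
          st$wiggle[m] * pi / D * cos(pi * u / D)
      }
      i <- seg_idx(st$t_hs[m], st$t_hs[m] + st$stance_dur[m], fs, n)
      if (length(i)) { psi[i] <- st$h_stance[m]; psidot[i] <- 0 }
      h_prev <- st$h_stance[m]
      if (k == length(mine)) {
        prev_end <- st$t_hs[m] + st$stance_dur[m]
        ie <- seg_idx(prev_end - 2 / fs, prev_end, fs, n)
        cur_off <- h_prev - (if (length(ie)) tv$h[ie[length(ie)]] else tv$h[n])
      }
    }
  }
  i <- seg_idx(prev_end, t[n] + 1, fs, n)
  if (length(i) && !is.na(cur_off)) {
    psi[i] <- tv$h[i] + cur_off; psidot[i] <- tv$hdot[i]
  }

  list(phi = numeric(n), phidot = numeric(n), th = th, thdot = thdot,
       psi = psi, psidot = psidot, anav = anav)
}

render_lumbar <- function(t, fs, steps, turns, tv, trunk, bouts) {
  n <- length(t)
  env <- numeric(n)
  phase <- numeric(n)
  if (!is.null(trunk) && !is.null(steps)) {
    for (b in trunk$bout) {
      st <- steps[steps$bout == b, , drop = FALSE]
      t0 <- min(st$t_to); t1 <- max(st$t_hs) + TERMINAL_STANCE
      env <- envelope_fill(env, t, t0, t1, BOUT_ENV_RAMP, fs)
      i <- seg_idx(t0, t1, fs, n)
      f <- trunk$f_stride[trunk$bout == b]
      phase[i] <- 2 * pi * f * (t[i] - t0)
    }
  }
  # transverse oscillation is suppressed through turns (trunk rotation
  # dominates); the taper sits outside the commanded interval
  supp <- env
  if (!is.null(turns)) {
    for (i in seq_len(nrow(turns))) {
      s0 <- turns$t_cmd_start[i]; s1 <- s0 + turns$duration_cmd[i]
      ii <- seg_idx(s0 - TURN_SUPP_RAMP, s1 + TURN_SUPP_RAMP, fs, n)
      if (!length(ii)) next
      w <- rep(0, length(ii))
      ri <- t[ii] < s0
      w[ri] <- 1 - (1 - cos(pi * (s0 - t[ii][ri]) / TURN_SUPP_RAMP)) / 2
      ro <- t[ii] > s1
      w[ro] <- 1 - (1 - cos(pi * (t[ii][ro] - s1) / TURN_SUPP_RAMP)) / 2
      w[ri & t[ii] < s0 - TURN_SUPP_RAMP] <- 1
      w[ro & t[ii] > s1 + TURN_SUPP_RAMP] <- 1
      supp[ii] <- pmin(supp[ii], w)
    }
  }

  amp <- function(col) {
    a <- numeric(n)
    if (is.null(trunk)) return(a)
    for (b in trunk$bout) {
      st <- steps[steps$bout == b, , drop = FALSE]
      i <- seg_idx(min(st$t_to), max(st$t_hs) + TERMINAL_STANCE, fs, n)
      a[i] <- trunk[[col]][trunk$bout == b] / 2
    }
    a
  }
  freq <- function() {
    f <- numeric(n)
    if (is.null(trunk)) return(f)
    for (b in trunk$bout) {
      st <- steps[steps$bout == b, , drop = FALSE]
      i <- seg_idx(min(st$t_to), max(st$t_hs) + TERMINAL_STANCE, fs, n)
      f[i] <- trunk$f_stride[trunk$bout == b]
    }
    f
  }
  A_cor <- amp("cor_rom"); A_sag <- amp("sag_rom"); A_tr <- amp("trans_rom")
  f_s <- freq()
  om <- 2 * pi * f_s   # rad/s oscillation frequency

  sinp <- sin(phase); cosp <- cos(phase)
  phi <- supp * A_cor * cosp
  phidot <- supp * A_cor * (-om * sinp)               # envelope rate ignored:
  th <- LUMBAR_LEAN + supp * A_sag * sinp             # ramps are slow and the
  thdot <- supp * A_sag * om * cosp                   # flanks carry no strides
  psi <- tv$h + supp * A_tr * sinp
  psidot <- tv$hdot + supp * A_tr * om * cosp

  anav <- matrix(0, n, 3)
  anav[, 3] <- env * LUMBAR_BOB * sin(2 * phase)
  list(phi = phi, phidot = phidot, th = th, thdot = thdot,
       psi = psi, psidot = psidot, anav = anav)
}

# euler channels -> body-frame specific force and angular rates (+ noise)
finish_stream <- function(site, t, ch, fs, noise) {
  n <- length(t)
  cphi <- cos(ch$phi * d2r); sphi <- sin(ch$phi * d2r)
  cth <- cos(ch$th * d2r); sth <- sin(ch$th * d2r)
  cpsi <- cos(ch$psi * d2r); spsi <- sin(ch$psi * d2r)

  gx <- ch$phidot - ch$psidot * sth
  gy <- ch$thdot * cphi + ch$psidot * cth * sphi
  gz <- -ch$thdot * sphi + ch$psidot * cth * cphi

  # world-frame specific force (movement + gravity), rotated into the body:
  # a_body = Rx(phi)^T Ry(theta)^T Rz(psi)^T a_world
  aw1 <- ch$anav[, 1]; aw2 <- ch$anav[, 2]; aw3 <- ch$anav[, 3] + GRAVITY
  b1 <- cpsi * aw1 + spsi * aw2
  b2 <- -spsi * aw1 + cpsi * aw2
  b3 <- aw3
  c1 <- cth * b1 - sth * b3
  c2 <- b2
  c3 <- sth * b1 + cth * b3
  a1 <- c1
  a2 <- cphi * c2 + sphi * c3
  a3 <- -sphi * c2 + cphi * c3

  accel <- cbind(a1, a2, a3)
  gyro <- cbind(gx, gy, gz)
  if (noise$accel_sd > 0)
    accel <- accel + matrix(stats::rnorm(3 * n, 0, noise$accel_sd), n, 3)
  if (noise$gyro_sd > 0)
    gyro <- gyro + matrix(stats::rnorm(3 * n, 0, noise$gyro_sd), n, 3)
  if (noise$gyro_bias_sd > 0)
    gyro <- sweep(gyro, 2, stats::rnorm(3, 0, noise$gyro_bias_sd), "+")
  colnames(accel) <- c("ax", "ay", "az"); colnames(gyro) <- c("gx", "gy", "gz")
  imu_stream(site, t, accel, gyro, fs)
}
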