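# Step detection, gait-bout assembly, stride segmentation, straight-walk flags.

#' Detect steps from foot pitch angular velocity
#'
#' Swing phases appear as positive bumps of pitch angular velocity
#' (dorsiflexion while the foot travels). Swing peaks are local maxima above
#' an adaptive threshold (a fraction of a robust amplitude estimate computed
#' in 10 s blocks, with a fixed floor so quiet periods yield nothing); toe-off
#' and heel-strike are the surrounding sign-structure landmarks: the last
#' non-positive sample before the peak and the first non-positive sample
#' after it.
#'
#' @param angles a `foot_angles` from [estimate_foot_angles()].
#' @param config a [dailygait_config()].
#' @return data.frame of step events ordered in time: `side`, `t_to`
#'   (toe-off), `t_peak` (swing peak), `t_hs` (heel-strike), s.
#' @export
detect_steps <- function(angles, config = dailygait_config()) {
  empty <- data.frame(side = character(0), t_to = numeric(0),
                      t_peak = numeric(0), t_hs = numeric(0))
  n <- length(angles$time)
  if (n < 3) return(empty)
  fs <- angles$fs
  w <- angles$pitch_rate
  # light smoothing against sample noise; 5 samples at 128 Hz keeps the bump
  w <- stats::filter(w, rep(1 / 5, 5), sides = 2)
  w[is.na(w)] <- 0
  w <- as.numeric(w)

  block <- max(1L, as.integer(config$step_thresh_window * fs))
  nb <- ceiling(n / block)
  bi <- rep(seq_len(nb), each = block)[seq_len(n)]
  q <- tapply(abs(w), bi, stats::quantile, probs = config$step_thresh_quantile,
              names = FALSE)
  thr <- pmax(config$step_thresh_frac * as.numeric(q), config$step_thresh_floor)[bi]

  pk <- which(w > thr & diff(c(-Inf, w)) > 0 & diff(c(w, Inf)) <= 0)
  if (!length(pk)) return(empty)
  # enforce minimum separation, keeping the larger peak
  o <- pk[order(-w[pk])]
  keep <- logical(length(w))
  sep <- as.integer(config$step_min_separation * fs)
  taken <- integer(0)
  for (i in o) {
    if (!length(taken) || all(abs(taken - i) >= sep)) {
      keep[i] <- TRUE; taken <- c(taken, i)
    }
  }
  pk <- which(keep)

  # refine each peak on the raw signal (the smoothed cusp is flat, so the
  # smoothed argmax can sit several samples off)
  wr <- angles$pitch_rate
  pk <- vapply(pk, function(i) {
    lo <- max(1L, i - 5L); (lo:min(n, i + 5L))[which.max(wr[lo:min(n, i + 5L)])]
  }, integer(1))
  pk <- sort(unique(pk))

  nonpos <- which(wr <= 0)
  if (!length(nonpos)) return(empty)
  j <- findInterval(pk, nonpos)
  ok <- j >= 1 & j < length(nonpos)
  pk <- pk[ok]; j <- j[ok]
  to_i <- nonpos[j]
  hs_i <- nonpos[j + 1]
  ok <- to_i < pk & hs_i > pk & (pk - to_i) < 1.5 * fs & (hs_i - pk) < 1.5 * fs
  pk <- pk[ok]; to_i <- to_i[ok]; hs_i <- hs_i[ok]
  if (!length(pk)) return(empty)
  dup <- duplicated(hs_i)
  pk <- pk[!dup]; to_i <- to_i[!dup]; hs_i <- hs_i[!dup]

  dt <- 1 / fs
  # sub-sample zero crossings around toe-off and heel-strike
  cross_up <- function(i) {   # w crosses 0 upward between i and i+1
    d <- wr[i + 1] - wr[i]
    angles$time[i] + ifelse(d > 1e-12, -wr[i] / d, 0.5) * dt
  }
  cross_dn <- function(i) {   # w crosses 0 downward between i-1 and i
    d <- wr[i] - wr[i - 1]
    angles$time[i - 1] + ifelse(d < -1e-12, wr[i - 1] / (-d), 0.5) * dt
  }
  # sub-sample swing peak: zero crossing of the first difference (the bump is
  # asymmetric, so a parabolic vertex would be biased toward its flatter side)
  t_peak <- vapply(pk, function(i) {
    lo <- max(2L, i - 4L); hi <- min(n - 1L, i + 4L)
    dw <- wr[(lo + 1L):(hi + 1L)] - wr[lo:hi]   # slope at midpoints lo+0.5, ...
    j <- which(dw[-length(dw)] >= 0 & dw[-1] < 0)
    if (!length(j)) return(angles$time[i])
    j <- j[which.min(abs(lo + j - 0.5 - i))]
    t1 <- angles$time[lo + j - 1L] + 0.5 * dt   # midpoint of difference j
    # both flanks of the velocity peak are locally linear; project each to its
    # zero crossing and prefer the falling flank unless it is under-resolved
    # (the commanded mid-swing pitch can sit close to foot-strike, squeezing
    # the falling flank below the sample spacing)
    tR <- NA_real_
    if (j + 2L <= length(dw) && dw[j + 2L] < dw[j + 1L])
      tR <- (t1 + dt) - dw[j + 1L] * dt / (dw[j + 2L] - dw[j + 1L])
    tL <- NA_real_
    if (j >= 2L && dw[j - 1L] > dw[j])
      tL <- t1 + dw[j] * dt / (dw[j - 1L] - dw[j])
    if (!is.na(tR) && tR >= t1 - 0.25 * dt && tR <= t1 + 1.25 * dt) return(tR)
    if (!is.na(tL) && tL >= t1 - 0.25 * dt && tL <= t1 + 1.25 * dt) return(tL)
    den <- dw[j] - dw[j + 1L]
    frac <- if (den > 1e-12) dw[j] / den else 0.5
    t1 + frac * dt
  }, numeric(1))

  data.frame(side = angles$side,
             t_to = cross_up(to_i),
             t_peak = t_peak,
             t_hs = cross_dn(hs_i),
             stringsAsFactors = FALSE)
}

#' Assemble candidate gait bouts from merged step times
#'
#' Steps from both feet, merged into one time-ordered sequence, chain into a
#' candidate bout while the gap from one step to the next stays under the
#' maximum (2.5 s by default); a candidate is kept as a gait bout only if it
#' lasts at least 3 s from first step to last step and contains at least 3
#' steps.
#'
#' @param step_times numeric vector of step times (any consistent step
#'   landmark; the pipeline uses heel-strike times), or a data.frame with a
#'   `t_hs` column.
#' @param config a [dailygait_config()].
#' @return data.frame with one row per bout: `bout`, `t_start`, `t_end`,
#'   `duration`, `n_steps`, `first`, `last` (indices into the sorted step
#'   sequence).
#' @export
assemble_bouts <- function(step_times, config = dailygait_config()) {
  if (is.data.frame(step_times)) step_times <- step_times$t_hs
  empty <- data.frame(bout = integer(0), t_start = numeric(0),
                      t_end = numeric(0), duration = numeric(0),
                      n_steps = integer(0), first = integer(0), last = integer(0))
  if (!length(step_times)) return(empty)
  ts <- sort(step_times)
  grp <- cumsum(c(1, as.integer(diff(ts) >= config$step_gap_max)))
  first <- match(unique(grp), grp)
  last <- length(grp) - match(unique(grp), rev(grp)) + 1L
  t0 <- ts[first]; t1 <- ts[last]
  nstep <- last - first + 1L
  keep <- (t1 - t0) >= config$bout_min_duration & nstep >= config$bout_min_steps
  out <- data.frame(bout = seq_len(sum(keep)), t_start = t0[keep],
                    t_end = t1[keep], duration = (t1 - t0)[keep],
                    n_steps = nstep[keep], first = first[keep], last = last[keep])
  stopifnot(all(out$duration >= config$bout_min_duration),
            all(out$n_steps >= config$bout_min_steps))
  out
}

# sample index of time t on the uniform grid of an angle/stream series
grid_idx <- function(series, t) {
  as.integer(floor((t - series$time[1]) * series$fs + 1e-6)) + 1L
}

# mean heading over a stance window [t0, t1] (headings are unwrapped, so a
# plain mean is safe)
stance_heading <- function(angles, t0, t1) {
  n <- length(angles$time)
  i0 <- min(max(grid_idx(angles, t0) + 1L, 1L), n)
  i1 <- min(max(grid_idx(angles, t1), 1L), n)
  if (i1 < i0) return(NA_real_)
  mean(angles$heading[i0:i1])
}

# linearly interpolated pitch (angle slopes reach ~200 deg/s, so nearest-
# sample reads would cost a degree at 128 Hz)
pitch_at <- function(angles, t) {
  n <- length(angles$time)
  i <- pmin(pmax(grid_idx(angles, t), 1L), n - 1L)
  f <- (t - angles$time[i]) * angles$fs
  f <- pmin(pmax(f, 0), 1)
  angles$pitch[i] * (1 - f) + angles$pitch[i + 1L] * f
}

# total overlap of [t0, t1] with a set of intervals
interval_overlap <- function(t0, t1, s, e) {
  if (!length(s)) return(0)
  sum(pmax(pmin(e, t1) - pmax(s, t0), 0))
}

#' Segment strides within a gait bout
#'
#' A stride runs from one heel-strike to the next heel-strike of the same
#' foot. Temporal phases come from the detected events (stance = heel-strike
#' to the same foot's next toe-off; swing is the complement; double support
#' sums the intervals when both feet are in stance). Angular quantities are
#' read from the foot angle series: mid-swing pitch at the swing-peak
#' instant, foot-strike angle at heel-strike, toe-off pitch at (and maximum
#' around) toe-off; toe-out is the mean stance heading minus the bout's
#' travel heading (the mean of all stance headings of both feet); the heading
#' change per stride is the difference between consecutive same-foot stance
#' headings. Stride length, swing elevation and lateral excursion come from
#' ZUPT-aided double integration of foot acceleration between foot-flats.
#'
#' @param bout one row of [assemble_bouts()] output.
#' @param steps the merged step table restricted to this bout's steps.
#' @param angles named list `list(left = , right = )` of `foot_angles`.
#' @param traj optional named list of [foot_trajectory] tables (computed
#'   internally by the pipeline; `NULL` skips the translation quantities).
#' @param config a [dailygait_config()].
#' @return data.frame of stride events (one row per stride of either foot,
#'   ordered by start time) with the temporal, angular and translation
#'   quantities plus `side`, `t_start`, `t_end`.
#' @export
segment_strides <- function(bout, steps, angles, traj = NULL,
                            config = dailygait_config()) {
  st <- steps[steps$t_hs >= bout$t_start - 1e-9 & steps$t_hs <= bout$t_end + 1e-9, ]
  st <- st[order(st$t_hs), ]
  empty <- NULL
  if (nrow(st) < 3) return(empty)

  # stance intervals per side: heel-strike to the same foot's next toe-off;
  # the final landing gets a nominal terminal stance window
  stance_iv <- lapply(c("left", "right"), function(s) {
    i <- which(st$side == s)
    if (!length(i)) return(data.frame(s = numeric(0), e = numeric(0)))
    data.frame(s = st$t_hs[i],
               e = c(st$t_to[i[-1]], st$t_hs[i[length(i)]] + 0.5))
  })
  names(stance_iv) <- c("left", "right")

  sh <- list()
  for (s in c("left", "right")) {
    iv <- stance_iv[[s]]
    sh[[s]] <- vapply(seq_len(nrow(iv)), function(k)
      stance_heading(angles[[s]], iv$s[k], iv$e[k]), numeric(1))
  }

  rows <- list()
  for (s in c("left", "right")) {
    i <- which(st$side == s)
    if (length(i) < 2) next
    other <- setdiff(c("left", "right"), s)
    ang <- angles[[s]]
    for (k in seq_len(length(i) - 1)) {
      m0 <- i[k]; m1 <- i[k + 1]
      t_start <- st$t_hs[m0]; t_end <- st$t_hs[m1]
      stride_time <- t_end - t_start
      stance_time <- st$t_to[m1] - t_start
      if (stance_time <= 0 || stance_time >= stride_time) next
      swing_time <- stride_time - stance_time
      # both feet grounded: own stance (heel-strike to own toe-off)
      # intersected with the other foot's stance intervals
      ds <- interval_overlap(t_start, st$t_to[m1],
                             stance_iv[[other]]$s, stance_iv[[other]]$e)
      h_this <- sh[[s]][k]
      h_next <- sh[[s]][k + 1]
      hchg <- abs(h_next - h_this)
      sgn <- if (s == "left") 1 else -1
      tow <- 0.1  # window for the max pitch around toe-off, s
      i_to <- min(max(grid_idx(ang, st$t_to[m1]), 1L), length(ang$time))
      iw <- max(1, i_to - as.integer(tow * ang$fs)):min(length(ang$time), i_to + as.integer(tow * ang$fs))
      p_to_max <- max(max(ang$pitch[iw]),
                      pitch_at(ang, st$t_to[m1] - tow),
                      pitch_at(ang, st$t_to[m1] + tow))
      geom <- c(NA_real_, NA_real_, NA_real_)
      toe_out <- NA_real_
      if (!is.null(traj) && nrow(traj[[s]])) {
        tr <- traj[[s]]
        hit <- which(tr$t0 < st$t_to[m1] & tr$t1 > st$t_hs[m1] - 1e-9)
        if (length(hit) == 1) {
          geom <- c(tr$length[hit], tr$elevation[hit], tr$lateral[hit])
          # toe-out: stance heading relative to the swing travel direction,
          # folded to (-180, 180]; positive = external rotation
          dlt <- (h_this - tr$dir[hit] + 180) %% 360 - 180
          toe_out <- sgn * dlt
        }
      }
      rows[[length(rows) + 1L]] <- list(
        side = s, t_start = t_start, t_end = t_end,
        stride_time = stride_time, step_duration = stride_time / 2,
        cadence = 120 / stride_time,
        stance_time = stance_time, swing_time = swing_time,
        double_support = ds,
        stance_pct = 100 * stance_time / stride_time,
        swing_pct = 100 * swing_time / stride_time,
        single_support_pct = 100 * (stance_time - ds) / stride_time,
        double_support_pct = 100 * ds / stride_time,
        stride_length = geom[[1]], gait_speed = geom[[1]] / stride_time,
        elevation = geom[[2]], lateral_excursion = geom[[3]],
        pitch_toe_off = pitch_at(ang, st$t_to[m1]),
        pitch_toe_off_max = p_to_max,
        pitch_midswing = pitch_at(ang, st$t_peak[m1]),
        foot_strike_angle = pitch_at(ang, st$t_hs[m1]),
        toe_out = toe_out,
        heading_change = hchg)
    }
  }
  if (!length(rows)) return(empty)
  out <- as.data.frame(data.table::rbindlist(rows))
  out <- out[order(out$t_start), ]
  rownames(out) <- NULL
  out
}

#' Flag straight-walking strides
#'
#' A stride counts as straight walking when the foot heading changed by no
#' more than the configured limit (20 degrees) over the stride and the stride
#' interval does not overlap any detected turn.
#'
#' @param strides stride table with `t_start`, `t_end`, `heading_change`.
#' @param turns turn table with `t_start`, `t_end` (possibly `NULL` or empty).
#' @param config a [dailygait_config()].
#' @return `strides` with logical columns `in_turn` and `straight` set.
#' @export
flag_straight_strides <- function(strides, turns, config = dailygait_config()) {
  if (is.null(strides) || !nrow(strides)) return(strides)
  tin <- rep(FALSE, nrow(strides))
  if (!is.null(turns) && nrow(turns)) {
    for (i in seq_len(nrow(turns)))
      tin <- tin | (strides$t_start < turns$t_end[i] &
                    strides$t_end > turns$t_start[i])
  }
  strides$in_turn <- tin
  strides$straight <- !tin &
    !is.na(strides$heading_change) &
    strides$heading_change <= config$straight_max_heading
  strides
}
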