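# Ground-truth event timelines: bouts, steps, strides, turns for a subject-week.

# Trapezoidal turn profile with ramp fraction TURN_RAMP_FRAC on each side.
# trap_frac: fraction of the total angle completed at normalized time u.
# trap_shape: normalized rate such that rate(t) = angle / duration * trap_shape(u).
TURN_RAMP_FRAC <- 0.3
TURN_EDGE_RATE <- 5     # deg/s crossing that delimits a detected turn
TERMINAL_STANCE <- 0.6  # s of stance rendered after the last step of a bout
SWING_INIT_FRAC <- 0.72 # initial-swing duration as a fraction of step time

trap_frac <- function(u, rho = TURN_RAMP_FRAC) {
  v <- 1 / (1 - rho)
  out <- numeric(length(u))
  out[u >= 1] <- 1
  i <- u > 0 & u < rho
  out[i] <- v * u[i]^2 / (2 * rho)
  i <- u >= rho & u <= 1 - rho
  out[i] <- v * (rho / 2 + (u[i] - rho))
  i <- u > 1 - rho & u < 1
  out[i] <- 1 - v * (1 - u[i])^2 / (2 * rho)
  out
}

trap_shape <- function(u, rho = TURN_RAMP_FRAC) {
  s <- pmin(u / rho, 1, (1 - u) / rho) / (1 - rho)
  s[u <= 0 | u >= 1] <- 0
  s
}

# Heading (deg) at times t given day-start heading and the day's turns
# (data.frame with t_cmd_start, duration_cmd, angle). Turns never overlap in
# time, so the heading is the cumulative angle of finished turns plus the
# partial ramp of an active one.
travel_heading_at <- function(t, turns, h0) {
  h <- rep(h0, length(t))
  if (is.null(turns) || nrow(turns) == 0) return(h)
  o <- order(turns$t_cmd_start)
  s <- turns$t_cmd_start[o]; d <- turns$duration_cmd[o]; a <- turns$angle[o]
  cum <- cumsum(a)
  j <- findInterval(t, s)
  started <- j > 0
  h[started] <- h[started] + cum[j[started]]
  u <- (t[started] - s[j[started]]) / d[j[started]]
  act <- u < 1
  h[started][act] <- h[started][act] -
    a[j[started]][act] * (1 - trap_frac(u[act]))
  h
}

# Truncated log-normal mean, E[X | X >= a].
trunc_lnorm_mean <- function(meanlog, sdlog, a) {
  exp(meanlog + sdlog^2 / 2) *
    stats::pnorm((meanlog + sdlog^2 - log(a)) / sdlog) /
    stats::pnorm((meanlog - log(a)) / sdlog)
}

rlnorm_trunc <- function(n, meanlog, sdlog, lo, hi = Inf) {
  x <- stats::rlnorm(n, meanlog, sdlog)
  bad <- which(x < lo | x > hi)
  while (length(bad)) {
    x[bad] <- stats::rlnorm(length(bad), meanlog, sdlog)
    bad <- bad[x[bad] < lo | x[bad] > hi]
  }
  x
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Draw the step-level structure of one gait bout starting at t0.
# latent/within: named lists of subject parameter means / within-subject SDs.
draw_bout <- function(t0, latent, within, spec) {
  M <- round(rlnorm_trunc(1, spec$bout_steps_meanlog, spec$bout_steps_sdlog,
                          spec$bout_steps_min, 400))
  side <- rep(c("left", "right"), length.out = M)
  if (stats::runif(1) < 0.5) side <- rev(side)
  u <- clamp(stats::rnorm(M, latent$step_time, within$step_time), 0.32, 1.2)
  swing_init <- SWING_INIT_FRAC * latent$step_time
  t_hs <- t0 + swing_init + c(0, cumsum(u[-1]))

  sf <- clamp(stats::rnorm(M, latent$stance_frac, within$stance_frac), 0.52, 0.72)
  stance <- rep(TERMINAL_STANCE, M)
  if (M > 2) {
    m <- seq_len(M - 2)
    stance[m] <- sf[m] * (t_hs[m + 2] - t_hs[m])
  }
  t_to <- c(t_hs[1] - swing_init, t_hs[2] - swing_init,
            if (M > 2) t_hs[seq_len(M - 2)] + stance[seq_len(M - 2)])
  swing_dur <- t_hs - t_to

  th_fs <- stats::rnorm(M, latent$foot_strike_angle, within$foot_strike_angle)
  th_to <- stats::rnorm(M, latent$pitch_toe_off, within$pitch_toe_off)
  th_fs <- pmax(th_fs, th_to + 4)
  th_ms <- clamp(stats::rnorm(M, latent$pitch_midswing, within$pitch_midswing),
                 th_to + 1, th_fs - 1)
  th_to[1:2] <- NA_real_; th_ms[1:2] <- NA_real_  # initial swings start flat

  list(
    step = seq_len(M), side = side, t_hs = t_hs, t_to = t_to,
    swing_dur = swing_dur, stance_dur = stance,
    th_to = th_to, th_ms = th_ms, th_fs = th_fs,
    swing_len = pmax(stats::rnorm(M, latent$stride_length, within$stride_length), 0.2),
    swing_elev = pmax(stats::rnorm(M, latent$elevation, within$elevation), 0.005),
    swing_lat = pmax(stats::rnorm(M, latent$lateral_excursion,
                                  within$lateral_excursion), 0.002),
    toe_out = clamp(stats::rnorm(M, latent$toe_out, within$toe_out), -15, 30),
    wiggle = clamp(stats::rnorm(M, 2.5, 0.5), 0, 6)
  )
}

# Time of the swing angular-velocity peak for each step of a bout.
swing_peak_times <- function(st) {
  r <- ifelse(is.na(st$th_to), 0.5,
              (st$th_ms - st$th_to) / (st$th_fs - st$th_to))
  st$t_to + r * st$swing_dur
}

#' Generate one subject-week ground-truth timeline
#'
#' Places gait bouts along each wear day by a renewal process at the requested
#' bout rate, fills each bout with alternating-foot steps whose stride
#' parameters are the subject's latent means plus within-subject noise, and
#' inserts turns — most taken while walking (spanning whole gait cycles, so the
#' strides they cover are flagged as turning), the rest standalone between
#' bouts. Heading evolves only through turns; every stride, turn and bout is
#' recorded in ground-truth event tables with the same schema the signal
#' pipeline emits, so pipeline outputs can be checked event by event.
#'
#' @param latent named list of subject-level parameter means (see
#'   [default_gait_params()] for the parameter set).
#' @param within named list of subject-level within-subject SDs.
#' @param spec a [cohort_spec()] (activity and design constants are read from
#'   it; group sizes are ignored here).
#' @param subject_id label written into the event tables.
#' @param seed optional integer seed.
#' @return object of class `subject_truth`: list with `steps`, `strides`,
#'   `turns`, `bouts` data.frames (all carrying a `day` column), `days`
#'   (per-day metadata: wear seconds, start heading), `latent`, `within`,
#'   `wear_hours`, `fs`.
#' @export
generate_subject_week <- function(latent, within, spec, subject_id = "S01",
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  W <- spec$wear_hours_per_day * 3600
  E_steps <- trunc_lnorm_mean(spec$bout_steps_meanlog, spec$bout_steps_sdlog,
                              spec$bout_steps_min)
  E_dur <- (E_steps - 1) * latent$step_time + 1.5
  gap_mean <- if (spec$bout_rate > 0) max(3600 / spec$bout_rate - E_dur - 2, 20) else Inf

  all_steps <- list(); all_strides <- list(); all_turns <- list()
  all_bouts <- list(); day_meta <- list()

  for (d in seq_len(spec$n_days)) {
    h0 <- stats::runif(1, 0, 360)
    bouts <- list()
    if (spec$bout_rate > 0) {
      t <- stats::rexp(1, 1 / gap_mean)
      repeat {
        st <- draw_bout(t, latent, within, spec)
        dur <- max(st$t_hs) + TERMINAL_STANCE - t
        if (t + dur > W) break
        bouts[[length(bouts) + 1L]] <- st
        t <- t + dur + 2 + stats::rexp(1, 1 / gap_mean)
        if (t > W) break
      }
    }
    nb <- length(bouts)

    # turns: total count at the commanded rate, walking turns first
    n_turns <- if (spec$turn_rate > 0) stats::rpois(1, spec$turn_rate * W / 3600) else 0L
    ang <- numeric(0); pk <- numeric(0)
    if (n_turns > 0) {
      mag <- pmax(stats::rnorm(n_turns, latent$turn_angle, within$turn_angle),
                  spec$turn_min_angle)
      ang <- mag * sample(c(-1, 1), n_turns, replace = TRUE)
      pk <- pmax(stats::rnorm(n_turns, latent$turn_peak_vel, within$turn_peak_vel), 25)
    }
    want_within <- stats::runif(n_turns) < spec$turn_within_frac & nb > 0

    # vectors accumulating placed turns
    t_cmd <- numeric(n_turns); t_dur <- numeric(n_turns)
    t_ang <- numeric(n_turns); t_pk <- numeric(n_turns)
    t_within <- logical(n_turns); t_bout <- rep(NA_integer_, n_turns)
    n_placed <- 0L
    occupied <- lapply(seq_len(nb), function(i) integer(0))  # step indices used
    bnd0 <- vapply(bouts, function(st) min(st$t_to) - 2, numeric(1))
    bnd1 <- vapply(bouts, function(st) max(st$t_hs) + TERMINAL_STANCE + 2, numeric(1))
    sa_s <- numeric(0); sa_e <- numeric(0)  # standalone intervals placed so far
    for (i in seq_len(n_turns)) {
      placed <- FALSE
      if (want_within[i]) {
        b <- sample.int(nb, 1)
        st <- bouts[[b]]
        M <- length(st$t_hs)
        d0 <- abs(ang[i]) / ((1 - TURN_RAMP_FRAC) * pk[i])
        k <- clamp(round(d0 / latent$step_time), 2, max(M - 5, 2))
        if (M - 1 - k >= 3) {
          occ <- logical(M)
          occ[occupied[[b]]] <- TRUE
          cand <- 3:(M - 1 - k)
          bad <- cumsum(occ)
          free <- cand[bad[cand + k] - c(0, bad)[cand] == 0]  # no occupied step in a:(a+k)
          if (length(free)) {
            a <- if (length(free) == 1) free else sample(free, 1)
            occupied[[b]] <- c(occupied[[b]], max(a - 1, 1):min(a + k + 1, M))
            s0 <- st$t_hs[a]; dcmd <- st$t_hs[a + k] - s0
            V <- abs(ang[i]) / ((1 - TURN_RAMP_FRAC) * dcmd)
            n_placed <- n_placed + 1L
            t_cmd[n_placed] <- s0; t_dur[n_placed] <- dcmd
            t_ang[n_placed] <- ang[i]; t_pk[n_placed] <- V
            t_within[n_placed] <- TRUE; t_bout[n_placed] <- b
            placed <- TRUE
          }
        }
      }
      if (!placed) {  # standalone turn in a gap
        dcmd <- abs(ang[i]) / ((1 - TURN_RAMP_FRAC) * pk[i])
        s0s <- stats::runif(60, 0, max(W - dcmd, 1))
        for (s0 in s0s) {
          if (any(s0 < bnd1 & s0 + dcmd > bnd0)) next
          if (length(sa_s) && any(s0 < sa_e + 1 & s0 + dcmd > sa_s - 1)) next
          n_placed <- n_placed + 1L
          t_cmd[n_placed] <- s0; t_dur[n_placed] <- dcmd
          t_ang[n_placed] <- ang[i]; t_pk[n_placed] <- pk[i]
          t_within[n_placed] <- FALSE
          sa_s <- c(sa_s, s0); sa_e <- c(sa_e, s0 + dcmd)
          break
        }
      }
    }
    turns <- NULL
    if (n_placed > 0) {
      ii <- seq_len(n_placed)
      ustar <- TURN_EDGE_RATE * TURN_RAMP_FRAC * t_dur[ii] / t_pk[ii]
      turns <- data.frame(
        t_cmd_start = t_cmd[ii], duration_cmd = t_dur[ii],
        t_start = t_cmd[ii] + ustar, t_end = t_cmd[ii] + t_dur[ii] - ustar,
        angle = t_ang[ii], peak_velocity = t_pk[ii],
        within_bout = t_within[ii], bout = t_bout[ii])
    }

    # trunk oscillation per bout
    trunk <- NULL
    if (nb > 0) {
      trunk <- data.frame(
        bout = seq_len(nb),
        cor_rom = pmax(stats::rnorm(nb, latent$trunk_cor_rom, within$trunk_cor_rom), 0.5),
        sag_rom = pmax(stats::rnorm(nb, latent$trunk_sag_rom, within$trunk_sag_rom), 0.5),
        trans_rom = pmax(stats::rnorm(nb, latent$trunk_trans_rom, within$trunk_trans_rom), 0.5),
        f_stride = NA_real_)
    }

    # assemble per-day tables with heading-dependent quantities
    steps_day <- list(); strides_day <- list(); bouts_day <- list()
    for (b in seq_len(nb)) {
      st <- bouts[[b]]
      M <- length(st$t_hs)
      trunk$f_stride[b] <- 1 / (2 * mean(diff(st$t_hs)))
      t_mid <- st$t_hs + st$stance_dur / 2
      sgn <- ifelse(st$side == "left", 1, -1)
      st$h_travel <- travel_heading_at(t_mid, turns, h0)
      st$h_swing <- travel_heading_at(st$t_to + st$swing_dur / 2, turns, h0)
      st$h_stance <- st$h_travel + sgn * st$toe_out
      st$bout <- b
      steps_day[[b]] <- st

      if (M > 2) {
        m <- seq_len(M - 2)
        stride_time <- st$t_hs[m + 2] - st$t_hs[m]
        stance_time <- st$t_to[m + 2] - st$t_hs[m]
        swing_time <- stride_time - stance_time
        # both feet grounded; the first stride's leading term would count
        # pre-bout standing (the other foot has not stepped yet), so it is 0
        ds1 <- pmax(st$t_to[m + 1] - st$t_hs[m], 0)
        ds1[1] <- 0
        ds <- ds1 + pmax(st$t_to[m + 2] - st$t_hs[m + 1], 0)
        hchg <- abs(st$h_stance[m + 2] - st$h_stance[m])
        tin <- rep(FALSE, length(m))
        if (!is.null(turns) && any(turns$within_bout & turns$bout == b)) {
          tw <- turns[turns$within_bout & turns$bout == b, ]
          for (i in seq_len(nrow(tw)))
            tin <- tin | (st$t_hs[m] < tw$t_end[i] & st$t_hs[m + 2] > tw$t_start[i])
        }
        pk_vel_f <- pi * trunk$f_stride[b]  # deg/s per deg of amplitude
        strides_day[[b]] <- list(
          bout = rep(b, length(m)), side = st$side[m],
          t_start = st$t_hs[m], t_end = st$t_hs[m + 2],
          stride_time = stride_time,
          step_duration = stride_time / 2,
          cadence = 120 / stride_time,
          stance_time = stance_time, swing_time = swing_time,
          double_support = ds,
          stance_pct = 100 * stance_time / stride_time,
          swing_pct = 100 * swing_time / stride_time,
          single_support_pct = 100 * (stance_time - ds) / stride_time,
          double_support_pct = 100 * ds / stride_time,
          stride_length = st$swing_len[m + 2],
          gait_speed = st$swing_len[m + 2] / stride_time,
          elevation = st$swing_elev[m + 2],
          lateral_excursion = st$swing_lat[m + 2],
          pitch_toe_off = st$th_to[m + 2],
          pitch_toe_off_max = pitch_toe_off_max_truth(st, m),
          pitch_midswing = st$th_ms[m + 2],
          foot_strike_angle = st$th_fs[m + 2],
          toe_out = st$toe_out[m],
          heading_change = hchg,
          trunk_cor_rom = trunk$cor_rom[b],
          trunk_sag_rom = trunk$sag_rom[b],
          trunk_trans_rom = trunk$trans_rom[b],
          trunk_cor_peak_vel = trunk$cor_rom[b] * pk_vel_f,
          trunk_sag_peak_vel = trunk$sag_rom[b] * pk_vel_f,
          trunk_trans_peak_vel = trunk$trans_rom[b] * pk_vel_f,
          in_turn = tin,
          straight = !tin & hchg <= 20)
      }
      bouts_day[[b]] <- list(
        bout = b, t_start = st$t_hs[1], t_end = st$t_hs[M],
        duration = st$t_hs[M] - st$t_hs[1],
        n_steps = M, n_strides = max(M - 2, 0))
    }

    # steps inside each turn (swing-peak time within the detected interval)
    if (!is.null(turns)) {
      turns$n_steps_in <- 0L
      if (nb > 0) {
        pk_t <- unlist(lapply(bouts, swing_peak_times))
        for (i in seq_len(nrow(turns)))
          turns$n_steps_in[i] <- sum(pk_t >= turns$t_start[i] & pk_t <= turns$t_end[i])
      }
      turns$duration <- turns$t_end - turns$t_start
      turns$magnitude <- abs(turns$angle)
      turns$mean_velocity <- turns$magnitude / turns$duration
      turns$direction <- ifelse(turns$angle > 0, "left", "right")
      turns$day <- d
      all_turns[[d]] <- turns
    }
    add_day <- function(lst) {
      if (!length(lst)) return(NULL)
      x <- as.data.frame(data.table::rbindlist(lst))
      x$day <- d
      x
    }
    all_steps[[d]] <- add_day(steps_day)
    all_strides[[d]] <- add_day(strides_day)
    all_bouts[[d]] <- add_day(bouts_day)
    day_meta[[d]] <- data.frame(day = d, wear_s = W, h0 = h0)
    if (!is.null(trunk)) trunk$day <- d
    attr(day_meta[[d]], "trunk") <- trunk
  }

  bind <- function(lst) {
    lst <- Filter(Negate(is.null), lst)
    if (!length(lst)) return(NULL)
    x <- as.data.frame(data.table::rbindlist(lst))
    x$subject_id <- subject_id
    x
  }
  out <- list(subject_id = subject_id,
              steps = bind(all_steps), strides = bind(all_strides),
              turns = bind(all_turns), bouts = bind(all_bouts),
              days = do.call(rbind, lapply(day_meta, function(x) x[, c("day", "wear_s", "h0")])),
              trunk = do.call(rbind, lapply(day_meta, function(x) attr(x, "trunk"))),
              latent = latent, within = within,
              wear_hours = spec$n_days * spec$wear_hours_per_day,
              n_days = spec$n_days, fs = spec$fs, noise = spec$noise)
  class(out) <- "subject_truth"
  out
}

# Truth value of the "maximum pitch around toe-off" quantity: the pitch
# trajectory dips to th_to at the toe-off instant, so the maximum over a
# +/- 0.1 s window is attained at one of the window edges.
pitch_toe_off_max_truth <- function(st, m) {
  w <- 0.1
  s <- st$stance_dur[m]
  po <- 0.30 * s                       # push-off duration
  pre <- ifelse(po > w,
                st$th_to[m + 2] * (1 - cos(pi * (po - w) / po)) / 2,
                0)
  D <- st$swing_dur[m + 2]
  thto <- st$th_to[m + 2]
  r <- (st$th_ms[m + 2] - thto) / (st$th_fs[m + 2] - thto)
  V <- pi * (st$th_fs[m + 2] - thto) / (2 * D)
  b1 <- r * D
  u <- pmin(w, b1)
  post <- thto + V * (2 * b1 / pi) * (1 - cos(pi * u / (2 * b1)))
  pmax(pre, post)
}

#' @export
print.subject_truth <- function(x, ...) {
  cat(sprintf("Ground-truth subject-week '%s': %d days, %.1f wear h\n",
              x$subject_id, x$n_days, x$wear_hours))
  cat(sprintf("  %d bouts, %d strides, %d turns\n",
              if (is.null(x$bouts)) 0L else nrow(x$bouts),
              if (is.null(x$strides)) 0L else nrow(x$strides),
              if (is.null(x$turns)) 0L else nrow(x$turns)))
  invisible(x)
}

#' Generate a ground-truthed synthetic cohort
#'
#' Draws subject-level latent parameters from the faller / non-faller group
#' distributions of the specification, generates each subject's week-long
#' event timeline, and assigns fall outcomes. With the default logistic
#' outcome, a subject's future-faller status is Bernoulli with log-odds linear
#' in the standardized subject-level latents named by the outcome
#' coefficients; with `mode = "group"` the faller group is the set of future
#' fallers, which pins the group effect sizes to the classification labels.
#'
#' @param spec a [cohort_spec()].
#' @param seed integer seed (overrides `spec$seed`).
#' @param timelines generate full event timelines (set `FALSE` for
#'   subject-level latents and labels only, which is much faster).
#' @return list of class `cohort`: `subjects` (list of `subject_truth`),
#'   `labels` (data.frame: subject_id, group, past_faller, future_faller,
#'   recurrent_faller, n_future_falls), `latents` (data.frame of subject-level
#'   means and within-SDs), `spec`.
#' @export
generate_cohort <- function(spec, seed = spec$seed, timelines = TRUE) {
  validate_cohort_spec(spec)
  if (!is.null(seed)) set.seed(seed)
  n <- spec$n_fallers + spec$n_nonfallers
  if (n == 0)
    return(structure(list(subjects = list(),
                          labels = data.frame(), latents = data.frame(),
                          spec = spec), class = "cohort"))
  group <- c(rep("nonfaller", spec$n_nonfallers), rep("faller", spec$n_fallers))
  ids <- sprintf("S%02d", seq_len(n))
  p <- spec$params

  lat <- matrix(NA_real_, n, nrow(p), dimnames = list(ids, p$param))
  wi <- matrix(NA_real_, n, nrow(p), dimnames = list(ids, paste0(p$param, "_within_sd")))
  for (j in seq_len(nrow(p))) {
    mu <- ifelse(group == "faller", p$mean_faller[j], p$mean_nonfaller[j])
    wmu <- ifelse(group == "faller", p$within_faller[j], p$within_nonfaller[j])
    lat[, j] <- stats::rnorm(n, mu, p$between_sd[j])
    wi[, j] <- pmax(stats::rnorm(n, wmu, p$within_between_sd[j]), 1e-4)
  }
  latents <- data.frame(subject_id = ids, group = group, lat, wi,
                        stringsAsFactors = FALSE, check.names = FALSE)

  # fall outcomes
  past <- group == "faller"
  oc <- spec$outcome
  if (identical(oc$mode, "group")) {
    future <- group == "faller"
  } else {
    Z <- cbind(lat, wi)
    cn <- names(oc$coefficients)
    missing_c <- setdiff(cn, colnames(Z))
    if (length(missing_c))
      stop("outcome coefficients name unknown latents: ", paste(missing_c, collapse = ", "))
    zs <- scale(Z[, cn, drop = FALSE])
    zs[is.nan(zs)] <- 0
    eta <- oc$intercept + drop(zs %*% oc$coefficients)
    future <- stats::runif(n) < stats::plogis(eta)
  }
  n_future <- ifelse(future, 1 + stats::rpois(n, oc$recurrent_rate), 0L)
  labels <- data.frame(subject_id = ids, group = group, past_faller = past,
                       future_faller = future, recurrent_faller = n_future >= 2,
                       n_future_falls = n_future, stringsAsFactors = FALSE)

  subjects <- vector("list", n)
  names(subjects) <- ids
  if (timelines) {
    for (i in seq_len(n)) {
      subjects[[i]] <- generate_subject_week(
        latent = as.list(lat[i, ]),
        within = stats::setNames(as.list(wi[i, ]), p$param),
        spec = spec, subject_id = ids[i])
    }
  }
  structure(list(subjects = subjects, labels = labels, latents = latents,
                 spec = spec), class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  n <- nrow(x$labels)
  cat(sprintf("Synthetic cohort: %d subjects (%d fallers, %d non-fallers by history)\n",
              n, sum(x$labels$group == "faller"), sum(x$labels$group == "nonfaller")))
  if (n) cat(sprintf("  future fallers: %d, recurrent: %d\n",
                     sum(x$labels$future_faller), sum(x$labels$recurrent_faller)))
  invisible(x)
}
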