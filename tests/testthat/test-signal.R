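# Foot-angle estimation, step detection, bout assembly, stride segmentation.

test_that("static foot: pitch equals the accelerometer inclination", {
  ang <- estimate_foot_angles(static_foot_stream(10))
  expect_lt(max(abs(ang$pitch - 10)), 0.1)
  expect_true(all(ang$stance))
  expect_lt(max(abs(diff(ang$pitch))), 1e-6)
})

test_that("pure vertical-axis rotation integrates to the commanded heading change", {
  fs <- 128; n <- 2 * fs
  g <- 9.80665
  gz <- c(rep(0, fs / 2), rep(20, fs), rep(0, n - fs - fs / 2))
  st <- imu_stream("right_foot", (seq_len(n) - 1) / fs,
                   cbind(0, 0, rep(g, n)), cbind(0, 0, gz), fs)
  ang <- estimate_foot_angles(st)
  expect_lt(abs((ang$heading[n] - ang$heading[1]) - 20), 0.2)
})

test_that("inputs are validated: lumbar site and too-short streams", {
  lum <- trapezoid_lumbar(90, 60)
  expect_error(estimate_foot_angles(lum), "foot site")
  short <- static_foot_stream(0, n_s = 1)
  short$time <- short$time[1:50]; short$accel <- short$accel[1:50, ]
  short$gyro <- short$gyro[1:50, ]
  expect_length(estimate_foot_angles(short)$pitch, 0)
})

test_that("motionless input yields no steps", {
  ang <- estimate_foot_angles(static_foot_stream(5, noise = 0.5))
  expect_equal(nrow(detect_steps(ang)), 0L)
})

test_that("rendered bouts give one detected swing per commanded step within 50 ms", {
  tr <- tiny_truth(seed = 12, wear_h = 0.15, turn_rate = 0, bout_rate = 25)
  st <- render_imu(tr, 1, noise = FALSE)
  for (side in c("left", "right")) {
    ang <- estimate_foot_angles(st[[paste0(side, "_foot")]])
    det <- detect_steps(ang)
    truth <- tr$steps[tr$steps$side == side, ]
    expect_equal(nrow(det), nrow(truth))
    expect_lt(max(abs(sort(det$t_hs) - sort(truth$t_hs))), 0.05)
    # recovered pitch landmarks against the commanded angles
    reg <- !is.na(truth$th_to)
    expect_lt(max(abs(pitch_at(ang, det$t_hs) - truth$th_fs)), 1.5)
    expect_lt(max(abs(pitch_at(ang, det$t_to[reg]) - truth$th_to[reg])), 1.5)
    expect_lt(max(abs(pitch_at(ang, det$t_peak[reg]) - truth$th_ms[reg])), 1.5)
  }
})

test_that("bout assembly applies the gap, duration and count rules exactly", {
  b1 <- assemble_bouts(c(0, 0.6, 1.2, 1.8, 2.4, 3.0))
  expect_equal(nrow(b1), 1L)
  expect_equal(b1$n_steps, 6L)
  expect_equal(b1$duration, 3)

  expect_equal(nrow(assemble_bouts(c(0, 1, 2))), 0L)   # 2 s < 3 s

  # one gap of 2.4 s keeps a single candidate; 2.6 s splits it
  base <- c(0, 0.8, 1.6, 2.4, 3.2)
  joined <- assemble_bouts(c(base, 3.2 + 2.4 + c(0, 0.8, 1.6, 2.4, 3.2)))
  expect_equal(nrow(joined), 1L)
  split <- assemble_bouts(c(base, 3.2 + 2.6 + c(0, 0.8, 1.6, 2.4, 3.2)))
  expect_equal(nrow(split), 2L)
  # the rule is strictly "less than": an exact 2.5 s gap splits
  exact <- assemble_bouts(c(base, 3.2 + 2.5 + c(0, 0.8, 1.6, 2.4, 3.2)))
  expect_equal(nrow(exact), 2L)
})

test_that("bout assembly equals the brute-force reference on random sequences", {
  set.seed(99)
  for (rep in 1:1000) {
    n <- sample(0:25, 1)
    times <- sort(runif(n, 0, 40))
    got <- assemble_bouts(times)
    ref <- bouts_reference(times)
    expect_equal(nrow(got), length(ref))
    if (nrow(got)) {
      expect_equal(got$n_steps, vapply(ref, length, integer(1)))
      expect_equal(got$t_start, vapply(ref, min, numeric(1)))
      expect_equal(got$t_end, vapply(ref, max, numeric(1)))
      # hard invariants on everything emitted
      expect_true(all(got$duration >= 3 & got$n_steps >= 3))
    }
  }
})

test_that("stride segmentation recovers commanded times and toe-out", {
  lat <- default_latent(step_time = 0.55, toe_out = 7)
  wi <- default_within(step_time = 1e-4, toe_out = 1e-4)
  tr <- tiny_truth(seed = 33, wear_h = 0.12, turn_rate = 0, bout_rate = 25,
                   latent = lat, within = wi)
  res <- process_day(render_imu(tr, 1, noise = FALSE))
  s <- res$strides
  expect_equal(nrow(s), nrow(tr$strides))
  expect_lt(max(abs(s$stride_time - 1.1)), 0.02)
  expect_lt(max(abs(s$toe_out - 7)), 1)
  expect_true(all(abs(s$stance_time + s$swing_time - s$stride_time) < 1 / 64))
  expect_true(all(s$double_support >= 0 & s$double_support < s$stride_time))
})

test_that("a bout with two same-foot heel-strikes yields exactly one stride per foot", {
  steps <- data.frame(
    side = c("left", "right", "left", "right"),
    t_to = c(-0.4, 0.15, 0.75, 1.25),
    t_peak = c(-0.2, 0.35, 0.95, 1.45),
    t_hs = c(0, 0.55, 1.1, 1.65))
  bout <- data.frame(t_start = 0, t_end = 1.65)
  fake_angles <- function(side) {
    n <- 4 * 128
    structure(list(time = (seq_len(n) - 1) / 128 - 1, pitch = numeric(n),
                   heading = numeric(n), pitch_rate = numeric(n),
                   stance = rep(TRUE, n),
                   flat_runs = data.frame(start = integer(0), end = integer(0)),
                   fs = 128, side = side), class = "foot_angles")
  }
  s <- segment_strides(bout, steps, list(left = fake_angles("left"),
                                         right = fake_angles("right")))
  expect_equal(nrow(s), 2L)
  expect_equal(sort(s$side), c("left", "right"))
  expect_equal(s$stride_time[s$side == "left"], 1.1)
})

test_that("straight-walking selection applies the 20-degree rule and turn overlap", {
  strides <- data.frame(t_start = c(0, 2, 4), t_end = c(1, 3, 5),
                        heading_change = c(25, 0, 5))
  turns <- data.frame(t_start = 4.5, t_end = 6)
  out <- flag_straight_strides(strides, turns)
  expect_equal(out$straight, c(FALSE, TRUE, FALSE))
  expect_equal(out$in_turn, c(FALSE, FALSE, TRUE))
  # boundary: exactly 20 degrees still counts as straight walking
  out20 <- flag_straight_strides(
    data.frame(t_start = 0, t_end = 1, heading_change = 20), turns = NULL)
  expect_true(out20$straight)
})

test_that("step detection stays reliable at default sensor noise", {
  set.seed(7)
  rec <- prec <- numeric(6)
  for (i in 1:6) {
    tr <- tiny_truth(seed = 100 + i, wear_h = 0.15, bout_rate = 25)
    res <- process_day(render_imu(tr, 1, noise = TRUE, seed = 200 + i))
    m <- event_match(tr$steps$t_hs, res$steps$t_hs, tol = 0.1)
    rec[i] <- m$recall; prec[i] <- m$precision
  }
  expect_gte(mean(rec, na.rm = TRUE), 0.98)
  expect_gte(mean(prec, na.rm = TRUE), 0.98)
})
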