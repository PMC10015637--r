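# The 52-measure catalog and the subject-week reduction.

test_that("the default catalog has 52 uniquely named entries in four domains", {
  cat0 <- measure_catalog()
  expect_equal(nrow(cat0), 52L)
  expect_equal(anyDuplicated(cat0$name), 0L)
  expect_setequal(unique(cat0$domain),
                  c("LowerBody", "LowerTrunk", "Turning", "Variability"))
  expect_equal(sum(cat0$domain == "LowerBody"), 16L)
  expect_equal(sum(cat0$domain == "LowerTrunk"), 6L)
  expect_equal(sum(cat0$domain == "Turning"), 8L)
  expect_equal(sum(cat0$domain == "Variability"), 22L)
  # the named measures of the study's winning models are present
  expect_true(all(c("pitch_midswing_mean", "toe_out_sd",
                    "turn_peak_velocity_mean", "cadence_sd", "stride_time_sd",
                    "double_support_pct_sd", "stance_pct_sd",
                    "pitch_toe_off_mean", "pitch_toe_off_max_mean",
                    "trunk_trans_rom_mean", "foot_strike_angle_sd",
                    "turn_angle_mean") %in% cat0$name))
  # coefficient-of-variation variant swaps the aggregation, not the structure
  catcv <- measure_catalog("cv")
  expect_equal(nrow(catcv), 52L)
  expect_true(all(grepl("_cv$", catcv$name[catcv$domain == "Variability"])))
})

stride_row <- function(stride_time, straight = TRUE, day = 1, ...) {
  base <- list(stride_time = stride_time, step_duration = stride_time / 2,
               cadence = 120 / stride_time, stance_pct = 62, swing_pct = 38,
               single_support_pct = 38, double_support_pct = 24,
               gait_speed = 1, stride_length = 1.05, elevation = 0.03,
               foot_strike_angle = 18, pitch_toe_off = -28,
               pitch_toe_off_max = -8, pitch_midswing = 10, toe_out = 7,
               lateral_excursion = 0.04, trunk_cor_rom = 6, trunk_sag_rom = 5,
               trunk_trans_rom = 8, trunk_cor_peak_vel = 18,
               trunk_sag_peak_vel = 15, trunk_trans_peak_vel = 24,
               heading_change = 2, in_turn = FALSE, straight = straight,
               day = day)
  as.data.frame(utils::modifyList(base, list(...)))
}

test_that("means and SDs pool straight strides with equal weight", {
  s <- rbind(stride_row(1.0), stride_row(1.1), stride_row(1.2))
  m <- compute_subject_measures(s, turns = NULL, bouts = NULL, wear_hours = 2)
  expect_equal(m$stride_time_mean, 1.1)
  expect_equal(m$stride_time_sd, sd(c(1, 1.1, 1.2)))   # sample SD, n - 1
  expect_equal(m$stride_time_sd, 0.1, tolerance = 1e-12)
  # identical strides: every variability entry is exactly zero
  s2 <- rbind(stride_row(1.05), stride_row(1.05), stride_row(1.05))
  m2 <- compute_subject_measures(s2, NULL, NULL, wear_hours = 2)
  vn <- measure_catalog()$name[measure_catalog()$domain == "Variability"]
  expect_true(all(unlist(m2[vn]) == 0))
})

test_that("the reduction is invariant to stride order and to non-straight strides", {
  set.seed(6)
  s <- do.call(rbind, lapply(rnorm(40, 1.05, 0.05), stride_row))
  m1 <- compute_subject_measures(s, NULL, NULL, 2)
  m2 <- compute_subject_measures(s[sample(nrow(s)), ], NULL, NULL, 2)
  expect_equal(m1[, setdiff(names(m1), "strides_per_hour")],
               m2[, setdiff(names(m2), "strides_per_hour")])
  # turning / turn-adjacent strides with wild values do not leak in
  junk <- stride_row(3.0, straight = FALSE, pitch_midswing = 60,
                     toe_out = 90, heading_change = 120, in_turn = TRUE)
  m3 <- compute_subject_measures(rbind(s, junk, junk), NULL, NULL, 2)
  cn <- measure_catalog()$name
  cn <- cn[!grepl("^turn_|^steps_in_turn", cn)]
  expect_equal(m1[, cn], m3[, cn])
})

test_that("a week with no straight strides yields missing values, not zeros", {
  s <- stride_row(1.0, straight = FALSE)
  m <- compute_subject_measures(s, NULL, NULL, 2)
  expect_true(m$missing_strides)
  expect_true(is.na(m$stride_time_mean))
  expect_false(is.na(m$strides_per_hour))
  expect_equal(m$strides_per_hour, 0.5)
  expect_error(compute_subject_measures(s, NULL, NULL, wear_hours = 0),
               "wear_hours")
})

test_that("turning measures pool all turns and activity rates divide by wear hours", {
  s <- rbind(stride_row(1.0), stride_row(1.1))
  turns <- data.frame(angle = c(90, -60), duration = c(1.5, 1.0),
                      peak_velocity = c(80, 70), n_steps_in = c(3, 2))
  bouts <- data.frame(bout = 1:3)
  m <- compute_subject_measures(s, turns, bouts, wear_hours = 4)
  expect_equal(m$turn_angle_mean, 75)      # magnitudes, signs dropped
  expect_equal(m$turn_angle_sd, sd(c(90, 60)))
  expect_equal(m$steps_in_turn_mean, 2.5)
  expect_equal(m$turns_per_hour, 0.5)
  expect_equal(m$bouts_per_hour, 0.75)
  expect_equal(m$strides_per_hour, 0.5)
})

test_that("generator within-subject variability is recovered from large truth samples", {
  lat <- default_latent(); wi <- default_within()
  spec <- cohort_spec(n_days = 1, wear_hours_per_day = 4)
  tr <- generate_subject_week(lat, wi, spec, seed = 31)
  s <- tr$strides[tr$strides$straight, ]
  expect_gt(nrow(s), 500)
  # stride time: per-stride SD is sqrt(2) * the per-step within-SD
  expect_lt(abs(sd(s$stride_time) / (sqrt(2) * wi$step_time) - 1), 0.10)
  expect_lt(abs(sd(s$pitch_midswing) / wi$pitch_midswing - 1), 0.10)
  expect_lt(abs(sd(s$toe_out) / wi$toe_out - 1), 0.10)
  expect_lt(abs(mean(s$pitch_midswing) - lat$pitch_midswing), 1)
  expect_lt(abs(mean(s$stride_time) / (2 * lat$step_time) - 1), 0.02)
})
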