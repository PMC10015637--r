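# Cohort specification and ground-truth timeline generation.

test_that("specification invariants are validated", {
  expect_error(cohort_spec(n_days = 0), "n_days")
  expect_error(cohort_spec(wear_hours_per_day = 0), "wear_hours")
  expect_error(cohort_spec(bout_rate = -1), "rates")
  bad <- default_gait_params()
  bad$between_sd[3] <- -1
  expect_error(cohort_spec(params = bad), "SDs")
  expect_s3_class(cohort_spec(), "cohort_spec")
})

test_that("an empty cohort is empty, not an error", {
  co <- generate_cohort(cohort_spec(n_fallers = 0, n_nonfallers = 0), seed = 1)
  expect_length(co$subjects, 0)
  expect_equal(nrow(co$labels), 0)
})

test_that("the default design is 17 fallers and 17 non-fallers", {
  co <- generate_cohort(cohort_spec(), seed = 2, timelines = FALSE)
  expect_equal(sum(co$labels$group == "faller"), 17)
  expect_equal(sum(co$labels$group == "nonfaller"), 17)
  expect_equal(sum(co$labels$past_faller), 17)
})

test_that("generation is reproducible from the seed", {
  spec <- cohort_spec(n_fallers = 2, n_nonfallers = 2, n_days = 1,
                      wear_hours_per_day = 0.3)
  a <- generate_cohort(spec, seed = 11)
  b <- generate_cohort(spec, seed = 11)
  expect_identical(a$latents, b$latents)
  expect_identical(a$subjects[[1]]$strides, b$subjects[[1]]$strides)
  expect_identical(a$subjects[[3]]$turns, b$subjects[[3]]$turns)
  c2 <- generate_cohort(spec, seed = 12)
  expect_false(identical(a$latents, c2$latents))
})

test_that("with no group effects the groups are statistically indistinguishable", {
  p <- default_gait_params()
  p$mean_faller <- p$mean_nonfaller
  p$within_faller <- p$within_nonfaller
  spec <- cohort_spec(params = p)
  set.seed(101)
  sig <- replicate(100, {
    co <- generate_cohort(spec, seed = sample.int(1e6, 1), timelines = FALSE)
    pv <- t.test(pitch_midswing ~ group, data = co$latents)$p.value
    pv < 0.01
  })
  expect_gte(sum(!sig), 97)
})

test_that("a planted 1.5-SD group effect is recovered by a t-test", {
  p <- default_gait_params()
  i <- p$param == "pitch_midswing"
  p$mean_faller[i] <- p$mean_nonfaller[i] - 1.5 * p$between_sd[i]
  spec <- cohort_spec(params = p)
  set.seed(202)
  rej <- replicate(200, {
    co <- generate_cohort(spec, seed = sample.int(1e6, 1), timelines = FALSE)
    t.test(pitch_midswing ~ group, data = co$latents)$p.value < 0.05
  })
  expect_gte(mean(rej), 0.95)
})

test_that("an inactive timeline has no strides and no turns", {
  tr <- tiny_truth(seed = 3, bout_rate = 0, turn_rate = 0, wear_h = 1)
  expect_null(tr$strides)
  expect_null(tr$turns)
  expect_null(tr$bouts)
})

test_that("bout placement realizes the commanded rate (renewal-process check)", {
  lat <- default_latent(); wi <- default_within()
  spec <- cohort_spec(n_days = 1, wear_hours_per_day = 4, turn_rate = 0)
  set.seed(55)
  counts <- vapply(1:50, function(i) {
    tr <- generate_subject_week(lat, wi, spec)
    if (is.null(tr$bouts)) 0L else nrow(tr$bouts)
  }, integer(1))
  rate <- sum(counts) / (50 * 4)
  se <- sqrt(spec$bout_rate / (50 * 4))
  expect_lt(abs(rate - spec$bout_rate), 3 * se)
})

test_that("default activity tuning lands near free-living daily-life rates", {
  spec <- cohort_spec(n_days = 3)
  co <- generate_cohort(spec, seed = 77)
  mm <- cohort_measures(co)
  expect_lt(abs(mean(mm$bouts_per_hour) - 7.82), 0.6)
  expect_lt(abs(mean(mm$turns_per_hour) - 20.19), 2)
  expect_gt(mean(mm$strides_per_hour), 149.9)
  expect_lt(mean(mm$strides_per_hour), 161.1)
})

test_that("timeline structure is internally consistent", {
  tr <- tiny_truth(seed = 9, wear_h = 1)
  s <- tr$strides
  expect_true(all(abs(s$stance_time + s$swing_time - s$stride_time) < 1e-9))
  expect_true(all(s$double_support >= 0 & s$double_support < s$stride_time))
  expect_true(all(s$t_end > s$t_start))
  # every stride lies inside its bout
  for (b in unique(s$bout)) {
    bo <- tr$bouts[tr$bouts$bout == b, ]
    expect_true(all(s$t_start[s$bout == b] >= bo$t_start - 1e-9))
    expect_true(all(s$t_end[s$bout == b] <= bo$t_end + 1e-9))
  }
  # standalone turns never intersect bouts
  sa <- tr$turns[!tr$turns$within_bout, ]
  for (i in seq_len(nrow(sa)))
    expect_false(any(tr$bouts$t_start < sa$t_end[i] &
                     tr$bouts$t_end > sa$t_start[i]))
  # strides overlapping a turn are flagged and excluded from straight walking
  expect_true(all(!s$straight[s$in_turn]))
  expect_true(all(s$straight == (!s$in_turn & s$heading_change <= 20)))
})
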