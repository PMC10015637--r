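# Faller labelling, logistic fitting, AUC machinery, group tests, power.

test_that("faller labels follow the fall-count rules", {
  log1 <- data.frame(subject_id = "a", past_6mo_falls = 0,
                     period_start = seq(0, 350, 14), period_end = seq(14, 364, 14),
                     n_falls = 0, n_near_falls = 1)
  lb <- label_fallers(log1)
  expect_false(lb$past_faller)
  expect_false(lb$future_faller)
  expect_false(lb$recurrent_faller)

  log2 <- log1; log2$n_falls[c(3, 9)] <- 1
  lb2 <- label_fallers(log2)
  expect_true(lb2$future_faller)
  expect_true(lb2$recurrent_faller)
  expect_equal(lb2$n_future_falls, 2)

  # near-falls never count
  log3 <- log1; log3$n_near_falls <- 5
  expect_false(label_fallers(log3)$future_faller)

  # partial coverage is flagged provisional
  lb4 <- label_fallers(log1[1:10, ])
  expect_true(lb4$provisional)
  expect_false(lb$provisional)

  expect_error(label_fallers(transform(log1, n_falls = -1)), "non-negative")
  bad <- log1; bad$period_start[2] <- 5
  expect_error(label_fallers(bad), "overlap")
})

test_that("the bundled synthetic cohort log reproduces a 25/9 future-faller split", {
  path <- system.file("extdata", "synthetic_falls.csv", package = "dailygait")
  lb <- label_fallers(read_falls_csv(path))
  expect_equal(nrow(lb), 34)
  expect_equal(sum(lb$future_faller), 25)
  expect_equal(sum(!lb$future_faller), 9)
  expect_equal(sum(lb$past_faller), 17)
  expect_equal(sum(lb$recurrent_faller), 20)
  # recurrent implies future faller
  expect_true(all(lb$future_faller[lb$recurrent_faller]))
})

test_that("intercept-only logistic fit matches the closed-form Bernoulli likelihood", {
  y <- rep(c(1, 0), c(25, 9))
  f <- fit_logistic(matrix(numeric(0), nrow = 34, ncol = 0), y)
  p <- 25 / 34
  logL <- 34 * (p * log(p) + (1 - p) * log(1 - p))
  expect_equal(f$logL, logL, tolerance = 1e-10)
  expect_equal(logL, -19.649, tolerance = 1e-3)
  expect_equal(bic_logistic(f$logL, 1, 34), 42.824, tolerance = 1e-3)
})

test_that("IRLS matches glm on random problems and flags pathologies", {
  set.seed(42)
  for (rep in 1:30) {
    n <- sample(30:80, 1); k <- sample(1:4, 1)
    x <- matrix(rnorm(n * k), n, k, dimnames = list(NULL, paste0("m", 1:k)))
    eta <- drop(x %*% rnorm(k, 0, 0.8))
    y <- rbinom(n, 1, plogis(eta))
    if (length(unique(y)) < 2) next
    f <- fit_logistic(x, y, standardize = FALSE)
    g <- suppressWarnings(glm.fit(cbind(1, x), y, family = binomial()))
    expect_equal(f$logL, -g$deviance / 2, tolerance = 1e-6)
  }
  # perfect separation is flagged, not an error
  xs <- matrix(c(-(5:1), 1:5), ncol = 1)
  ys <- rep(0:1, each = 5)
  fs <- fit_logistic(xs, ys)
  expect_true(fs$separated)
  # constant outcome is an error
  expect_error(fit_logistic(xs, rep(1, 10)), "constant")
  # z-scoring does not change the maximized likelihood
  set.seed(9)
  x2 <- matrix(rnorm(120), 40, 3); y2 <- rbinom(40, 1, 0.5)
  expect_equal(fit_logistic(x2, y2, standardize = TRUE)$logL,
               fit_logistic(x2, y2, standardize = FALSE)$logL, tolerance = 1e-6)
})

test_that("empirical AUC equals pair counting, the trapezoidal ROC area, and pROC", {
  expect_equal(empirical_auc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
  expect_equal(empirical_auc(rep(2, 6), rep(0:1, 3)), 0.5)
  expect_equal(empirical_auc(c(1, 2, 2, 3), c(0, 0, 1, 1)), 0.875)

  trapz_auc <- function(scores, y) {
    r <- dailygait:::roc_points(scores, y)
    sum(diff(r$fpr) * (utils::head(r$tpr, -1) + utils::tail(r$tpr, -1)) / 2)
  }
  set.seed(11)
  for (rep in 1:20) {
    n <- sample(10:60, 1)
    scores <- sample(1:8, n, replace = TRUE) # plenty of ties
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    a <- empirical_auc(scores, y)
    expect_equal(a, trapz_auc(scores, y), tolerance = 1e-12)
    # invariance under strictly increasing transforms
    expect_identical(a, empirical_auc(exp(scores / 2) + 5, y))
    if (requireNamespace("pROC", quietly = TRUE)) {
      pr <- pROC::auc(pROC::roc(y, scores, quiet = TRUE, direction = "<"))
      expect_equal(a, as.numeric(pr), tolerance = 1e-12)
    }
  }
  expect_error(empirical_auc(1:4, rep(1, 4)), "both classes")
})

test_that("bootstrap AUC interval is seeded, ordered and degenerate-safe", {
  set.seed(3)
  scores <- c(rnorm(20), rnorm(20, 2)); y <- rep(0:1, each = 20)
  ci1 <- auc_ci(scores, y, n_boot = 500, seed = 7)
  ci2 <- auc_ci(scores, y, n_boot = 500, seed = 7)
  expect_identical(ci1, ci2)
  expect_lte(ci1$lower, ci1$auc)
  expect_gte(ci1$upper, ci1$auc)
  # perfect separation at decent n pins the upper limit at 1
  ps <- c(1:20, 41:60); yp <- rep(0:1, each = 20)
  expect_equal(auc_ci(ps, yp, n_boot = 200, seed = 1)$upper, 1)
  # a binary predictor's AUC is (sensitivity + specificity) / 2
  set.seed(8)
  yb <- rbinom(80, 1, 0.6); xb <- ifelse(runif(80) < 0.75, yb, 1 - yb)
  sens <- mean(xb[yb == 1] == 1); spec <- mean(xb[yb == 0] == 0)
  expect_equal(empirical_auc(xb, yb), (sens + spec) / 2, tolerance = 1e-12)
  # too-small class: flagged
  expect_true(auc_ci(c(1, 2, 3), c(0, 1, 1), n_boot = 10)$degenerate)
})

test_that("best-subsets screening matches an exhaustive glm reference", {
  set.seed(21)
  n <- 60; p <- 12
  x <- as.data.frame(matrix(rnorm(n * p), n, p))
  names(x) <- sprintf("m%02d", 1:p)
  y <- rbinom(n, 1, plogis(0.8 * x$m01 - 0.8 * x$m02))
  sc <- best_subsets(x, y, sizes = 2:3, top_per_size = 15, n_boot = 0)
  ref <- best_subsets_reference(x, y, sizes = 2:3, top_per_size = 15)
  for (k in c("2", "3")) {
    got <- sc$models$measures[sc$models$size == as.integer(k)]
    expect_equal(got, ref[[k]])
  }
})

test_that("best-subsets equals the reference on many small random instances", {
  set.seed(77)
  for (rep in 1:50) {
    n <- sample(40:70, 1); p <- sample(5:9, 1)
    x <- as.data.frame(matrix(rnorm(n * p), n, p))
    names(x) <- sprintf("v%02d", seq_len(p))
    y <- rbinom(n, 1, plogis(rnorm(1) + 0.7 * x[[1]]))
    if (length(unique(y)) < 2) next
    k <- sample(2:3, 1)
    sc <- best_subsets(x, y, sizes = k, top_per_size = 5, n_boot = 0)
    ref <- best_subsets_reference(x, y, sizes = k, top_per_size = 5)
    expect_equal(sc$models$measures, ref[[as.character(k)]])
  }
})

test_that("screening cardinality: fewer subsets than requested, and 45 + 10 at defaults", {
  set.seed(5)
  n <- 40
  x5 <- as.data.frame(matrix(rnorm(n * 5), n, 5)); names(x5) <- paste0("a", 1:5)
  y <- rbinom(n, 1, plogis(x5$a1))
  sc5 <- best_subsets(x5, y, sizes = 2, top_per_size = 15, n_boot = 0)
  expect_equal(nrow(sc5$models), choose(5, 2))
  expect_false(is.unsorted(sc5$models$bic))

  x12 <- as.data.frame(matrix(rnorm(n * 12), n, 12)); names(x12) <- paste0("b", 1:12)
  sc12 <- best_subsets(x12, y, sizes = 2:4, top_per_size = 15, top_auc = 10,
                       n_boot = 0)
  expect_equal(nrow(sc12$models), 45L)
  expect_equal(table(sc12$models$size), table(rep(2:4, each = 15)),
               ignore_attr = TRUE)
  expect_length(sc12$top, 10L)
  expect_equal(sc12$models$rank[sc12$top], 1:10)
})

test_that("model ranking sorts by AUC and reports selection frequencies", {
  models <- data.frame(
    measures = c("a + b", "a + c", "b + c", "a + d"),
    bic = c(10, 12, 8, 11),
    auc = c(0.9, 0.9, 0.8, 0.95))
  r <- rank_models(models, top = 10)
  expect_equal(length(r), 4)            # fewer models than requested
  expect_equal(models$measures[r[1]], "a + d")
  expect_equal(models$measures[r[2]], "a + b")  # AUC tie broken by lower BIC
  # frequency counting across a ranked set
  freq <- table(unlist(strsplit(models$measures[r], " \\+ ")))
  expect_equal(unname(freq[["a"]]), 3)
})

test_that("fall_screen methods work: print, summary, coef, predict, plot", {
  set.seed(13)
  pc <- planted_cohort_measures(seed = 13, n_days = 1)
  sc <- best_subsets(pc$measures[, candidate_measures], pc$y,
                     n_boot = 100, seed = 2)
  expect_output(print(sc), "Best-subsets logistic screen")
  expect_output(print(summary(sc)), "selection frequency")
  expect_type(coef(sc), "double")
  pr <- predict(sc)
  expect_true(all(pr >= 0 & pr <= 1))
  expect_gt(empirical_auc(predict(sc, type = "link"), pc$y), 0.8)
  tf <- tempfile(fileext = ".png")
  grDevices::png(tf); plot(sc); grDevices::dev.off()
  expect_true(file.exists(tf))
  unlink(tf)
})

test_that("group comparisons route by type and normality", {
  set.seed(4)
  g <- rep(c("a", "b"), each = 40)
  # binary variable -> chi-squared
  expect_equal(compare_groups(rbinom(80, 1, 0.5), g)$test, "chi-squared")
  # heavily skewed -> Mann-Whitney
  expect_equal(compare_groups(rlnorm(80, 0, 1.5), g)$test, "mann-whitney")
  # normal draws -> t-test (seeded so the Shapiro route is stable)
  set.seed(10)
  expect_equal(compare_groups(rnorm(80), g)$test, "t-test")
  # tiny groups skip the normality test and use Mann-Whitney
  expect_equal(compare_groups(c(1, 2, 1.4, 2.2), c("a", "a", "b", "b"))$test,
               "mann-whitney")
  expect_error(compare_groups(rnorm(9), rep(c("a", "b", "c"), 3)), "two groups")
})

test_that("type-I error of the routed comparison is near nominal", {
  set.seed(1234)
  p <- replicate(100, compare_groups(rnorm(120), rep(c("x", "y"), 60))$p.value)
  expect_gte(sum(p > 0.05), 94)
})

test_that("power analysis: noncentral-t sample size", {
  expect_equal(suppressMessages(
    power_sample_size(0.59, 0.04, 0.54, 0.03, alpha = 0.05, power = 0.95,
                      sided = "one")), 12)
  expect_error(suppressMessages(power_sample_size(0.5, 0.04, 0.5, 0.03)),
               "effect size zero")
  # two-sided needs more subjects; reference: stats::power.t.test
  d <- (0.59 - 0.54) / sqrt((0.04^2 + 0.03^2) / 2)
  ref <- ceiling(stats::power.t.test(delta = d, sd = 1, sig.level = 0.05,
                                     power = 0.95,
                                     alternative = "two.sided")$n)
  n2 <- power_sample_size(0.59, 0.04, 0.54, 0.03, sided = "two")
  expect_equal(n2, ref)
  expect_gt(n2, 12)
  # monotone in power and effect size
  n_lo <- suppressMessages(power_sample_size(0.59, 0.04, 0.54, 0.03, power = 0.8))
  expect_lte(n_lo, 12)
  n_big <- suppressMessages(power_sample_size(0.64, 0.04, 0.54, 0.03))
  expect_lte(n_big, 12)
})

test_that("adding a pure-noise measure usually increases BIC", {
  set.seed(2024)
  worse <- replicate(50, {
    n <- 200
    x <- matrix(rnorm(n * 3), n, 3)
    y <- rbinom(n, 1, plogis(x[, 1] - x[, 2]))
    f2 <- fit_logistic(x[, 1:2], y)
    f3 <- fit_logistic(x, y)
    bic_logistic(f3$logL, 4, n) > bic_logistic(f2$logL, 3, n)
  })
  expect_gte(mean(worse), 0.9)
})
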