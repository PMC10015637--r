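# Fall-outcome labelling and best-subsets logistic screening of gait measures.

#' Label fallers from a falls log
#'
#' Converts a falls log (6-month retrospective count plus prospective follow-up
#' reports covering 12 months at roughly 2-week intervals) into the three
#' binary labels used downstream: past faller (>= 1 fall in the 6 months before
#' monitoring), future faller (>= 1 fall during follow-up) and recurrent faller
#' (>= 2 falls during follow-up). Near-falls are carried in the log but never
#' contribute to a label. A fall is an event that ends with the person
#' unintentionally on the ground or another lower level.
#'
#' @param falls data.frame with columns `subject_id`, `past_6mo_falls`,
#'   `period_start`, `period_end`, `n_falls` and optionally `n_near_falls`;
#'   one row per follow-up reporting period. `period_start`/`period_end` may be
#'   `Date`s or numeric day offsets.
#' @param followup_days nominal length of the prospective window (days);
#'   subjects whose reported periods cover less than 95% of it get
#'   `provisional = TRUE`.
#' @return data.frame with one row per subject: `subject_id`, `past_faller`,
#'   `future_faller`, `recurrent_faller`, `n_future_falls`, `provisional`.
#' @examples
#' log <- data.frame(subject_id = "s1", past_6mo_falls = 0,
#'                   period_start = seq(0, 350, 14), period_end = seq(14, 364, 14),
#'                   n_falls = 0, n_near_falls = 0)
#' log$n_falls[3] <- 2
#' label_fallers(log)
#' @export
label_fallers <- function(falls, followup_days = 365) {
  req <- c("subject_id", "past_6mo_falls", "period_start", "period_end", "n_falls")
  miss <- setdiff(req, names(falls))
  if (length(miss)) stop("falls log is missing columns: ", paste(miss, collapse = ", "))
  if (any(falls$n_falls < 0) || any(falls$past_6mo_falls < 0))
    stop("fall counts must be non-negative")
  if (!is.null(falls$n_near_falls) && any(falls$n_near_falls < 0))
    stop("near-fall counts must be non-negative")

  out <- lapply(split(falls, falls$subject_id), function(d) {
    o <- order(as.numeric(d$period_start))
    d <- d[o, ]
    s <- as.numeric(d$period_start); e <- as.numeric(d$period_end)
    if (any(e < s)) stop("period_end before period_start for subject ", d$subject_id[1])
    if (nrow(d) > 1 && any(s[-1] < e[-nrow(d)] - 1e-9))
      stop("overlapping follow-up periods for subject ", d$subject_id[1])
    covered <- sum(e - s)
    nf <- sum(d$n_falls)
    data.frame(
      subject_id = d$subject_id[1],
      past_faller = d$past_6mo_falls[1] >= 1,
      future_faller = nf >= 1,
      recurrent_faller = nf >= 2,
      n_future_falls = nf,
      provisional = covered < 0.95 * followup_days,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Maximum-likelihood logistic regression by IRLS
#'
#' Plain logistic regression fitted with iteratively reweighted least squares.
#' Written out explicitly (rather than delegating to [stats::glm()]) so the
#' screening stage controls convergence, standardization and separation
#' handling; `glm` serves as an independent cross-check in the test-suite.
#'
#' @param x numeric matrix or data.frame of predictors (no intercept column).
#' @param y binary outcome (0/1 or logical).
#' @param standardize z-score columns before fitting (the default); with a
#'   monotone link this changes coefficients but neither the maximized
#'   log-likelihood nor the ranking of fitted scores.
#' @param max_iter,tol IRLS iteration cap and convergence tolerance on
#'   `max(abs(delta beta))`.
#' @return list with `coefficients` (named, intercept first), `logL`,
#'   `converged`, `separated`, `singular`, `iterations`, `fitted`, `eta`, `n`.
#' @export
fit_logistic <- function(x, y, standardize = TRUE, max_iter = 100, tol = 1e-8) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("y must be binary (0/1 or logical)")
  if (length(unique(y)) < 2L) stop("y is constant: no discrimination possible")
  if (nrow(x) != length(y)) stop("nrow(x) != length(y)")
  n <- length(y)
  if (standardize && ncol(x) > 0) {
    mu <- colMeans(x); sg <- apply(x, 2, stats::sd)
    sg[sg == 0] <- 1
    x <- sweep(sweep(x, 2, mu), 2, sg, "/")
  }
  X <- cbind(`(Intercept)` = 1, x)
  p <- ncol(X)
  if (n < p + 1) stop("need n >= p + 1 observations")
  singular <- qr(X)$rank < p

  beta <- numeric(p)
  beta[1] <- stats::qlogis(mean(y))
  converged <- FALSE
  it <- 0L
  if (!singular) {
    for (it in seq_len(max_iter)) {
      eta <- drop(X %*% beta)
      mu <- stats::plogis(eta)
      w <- pmax(mu * (1 - mu), 1e-10)
      # Newton step: solve (X'WX) d = X'(y - mu)
      XtW <- t(X * w)
      d <- tryCatch(solve(XtW %*% X, crossprod(X, y - mu)),
                    error = function(e) NULL)
      if (is.null(d)) { singular <- TRUE; break }
      beta <- beta + drop(d)
      if (max(abs(d)) < tol) { converged <- TRUE; break }
    }
  }
  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  # quasi-complete separation: coefficients diverge, fitted values pinned at 0/1
  separated <- !singular && !converged &&
    (max(abs(beta[-1])) > 12 || all(abs(mu - y) < 1e-4))
  logL <- sum(y * log(pmax(mu, 1e-300)) + (1 - y) * log(pmax(1 - mu, 1e-300)))
  names(beta) <- colnames(X)
  list(coefficients = beta, logL = logL, converged = converged,
       separated = separated, singular = singular, iterations = it,
       fitted = mu, eta = eta, n = n)
}

#' Bayesian Information Criterion for a fitted logistic model
#'
#' `BIC = -2 logL + p log(n)` where the parameter count `p` includes the
#' intercept and `n` is the number of complete-case subjects.
#'
#' @param logL maximized log-likelihood.
#' @param n_param number of estimated parameters (intercept included).
#' @param n sample size.
#' @export
bic_logistic <- function(logL, n_param, n) -2 * logL + n_param * log(n)

#' Empirical area under the ROC curve
#'
#' Probability that a randomly chosen positive scores above a randomly chosen
#' negative, counting ties as one half: `(concordant + 0.5 ties) / (n1 * n0)`.
#' Identical to the trapezoidal area under the empirical ROC curve, and
#' invariant under strictly increasing transforms of the scores.
#'
#' @param scores numeric risk scores (higher = more positive-like).
#' @param y binary labels.
#' @return AUC in `[0, 1]`.
#' @examples
#' empirical_auc(c(1, 2, 2, 3), c(0, 0, 1, 1)) # 0.875
#' @export
empirical_auc <- function(scores, y) {
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("y must be binary")
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)                       # midranks handle ties
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Stratified bootstrap confidence interval for the empirical AUC
#'
#' Percentile interval from `n_boot` bootstrap resamples drawn within class
#' (the class balance is fixed by design, so resampling is stratified).
#'
#' @inheritParams empirical_auc
#' @param n_boot number of resamples.
#' @param conf confidence level.
#' @param seed optional integer; when given the interval is reproducible.
#' @return list with `lower`, `upper`, `auc`, `degenerate` (TRUE when a class
#'   has fewer than 2 members and the interval is not meaningful).
#' @export
auc_ci <- function(scores, y, n_boot = 2000, conf = 0.95, seed = NULL) {
  y <- as.numeric(y)
  auc <- empirical_auc(scores, y)
  i1 <- which(y == 1); i0 <- which(y == 0)
  if (length(i1) < 2 || length(i0) < 2)
    return(list(lower = NA_real_, upper = NA_real_, auc = auc, degenerate = TRUE))
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(seed)
  }
  s1 <- scores[i1]; s0 <- scores[i0]
  n1 <- length(s1); n0 <- length(s0)
  stat <- vapply(seq_len(n_boot), function(b) {
    b1 <- s1[sample.int(n1, n1, replace = TRUE)]
    b0 <- s0[sample.int(n0, n0, replace = TRUE)]
    r <- rank(c(b1, b0))
    (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }, numeric(1))
  a <- (1 - conf) / 2
  q <- unname(stats::quantile(stat, c(a, 1 - a), type = 7))
  list(lower = q[1], upper = q[2], auc = auc, degenerate = FALSE)
}

#' Best-subsets logistic screening of gait measures for future falls
#'
#' The model-selection stage of the daily-life gait analysis: every subset of
#' `sizes` measures is fitted by logistic regression on z-scored predictors,
#' the `top_per_size` lowest-BIC converged models are retained for each subset
#' size, retained models are scored by empirical AUC (with a stratified
#' bootstrap confidence interval), and the `top_auc` highest-AUC models are
#' ranked. With the default sizes 2, 3 and 4 and 15 models per size the screen
#' retains 45 candidate models and ranks the top 10, and reports how often each
#' measure is selected across the ranked models.
#'
#' Subsets whose fit is singular (collinear) are dropped from the ranking;
#' quasi-complete separation is flagged but the model is kept, since with small
#' cohorts and strong measures near-separation is expected.
#'
#' @param x data.frame or matrix of candidate measures (columns named), one row
#'   per subject. Rows with missing values are dropped (complete cases).
#' @param y future-faller labels (logical or 0/1).
#' @param sizes subset sizes to enumerate.
#' @param top_per_size models retained per size by ascending BIC (ties broken
#'   lexicographically on measure names).
#' @param top_auc models ranked by descending AUC (ties: lower BIC, then
#'   lexicographic).
#' @param n_boot bootstrap resamples for each retained model's AUC interval;
#'   set to 0 to skip intervals.
#' @param seed seed for the bootstrap intervals.
#' @return An object of class `fall_screen`: list with `models` (data.frame of
#'   retained candidates: size, measures, logL, bic, auc, auc_lo, auc_hi,
#'   converged, separated, rank), `coefficients` (list of named coefficient
#'   vectors on the z-scored scale), `top` (row indices of the ranked models),
#'   `selection_freq` (named counts over the ranked models), `n`, `dropped`
#'   (subjects lost to missingness), `scale` (centers/scales used), `x`, `y`.
#' @seealso [rank_models()], [empirical_auc()], [fit_logistic()]
#' @export
best_subsets <- function(x, y, sizes = 2:4, top_per_size = 15, top_auc = 10,
                         n_boot = 2000, seed = 1L) {
  x <- as.data.frame(x)
  if (is.null(names(x)) || any(!nzchar(names(x)))) stop("measure columns must be named")
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("y must be binary")
  cc <- stats::complete.cases(x) & !is.na(y)
  dropped <- sum(!cc)
  x <- x[cc, , drop = FALSE]; y <- y[cc]
  n <- nrow(x)
  p <- ncol(x)
  if (p < 2) stop("need at least 2 candidate measures")
  sizes <- sort(unique(as.integer(sizes)))
  if (any(sizes > p)) {
    warning("subset sizes larger than the number of measures were dropped")
    sizes <- sizes[sizes <= p]
  }
  if (length(unique(y)) < 2) stop("y is constant: no discrimination possible")

  ctr <- colMeans(x); scl <- apply(x, 2, stats::sd); scl[scl == 0] <- 1
  xs <- as.matrix(sweep(sweep(x, 2, ctr), 2, scl, "/"))
  nm <- colnames(xs)

  if (any(choose(p, sizes) > 5e6))
    stop("subset space too large: choose(", p, ", ", max(sizes), ") models")
  rows <- list(); coefs <- list()
  for (k in sizes) {
    combos <- utils::combn(p, k)
    m <- ncol(combos)
    res_bic <- numeric(m); res_logL <- numeric(m)
    res_conv <- logical(m); res_sep <- logical(m); res_sing <- logical(m)
    fits <- vector("list", m)
    for (j in seq_len(m)) {
      f <- fit_logistic(xs[, combos[, j], drop = FALSE], y, standardize = FALSE)
      res_logL[j] <- f$logL
      res_bic[j] <- bic_logistic(f$logL, k + 1, n)
      res_conv[j] <- f$converged || f$separated  # separated fits kept, flagged
      res_sep[j] <- f$separated
      res_sing[j] <- f$singular
      fits[[j]] <- f
    }
    labels <- apply(combos, 2, function(ix) paste(nm[ix], collapse = " + "))
    keep <- which(!res_sing & res_conv)
    ord <- keep[order(res_bic[keep], labels[keep])]
    ord <- utils::head(ord, top_per_size)
    for (j in ord) {
      f <- fits[[j]]
      rows[[length(rows) + 1L]] <- data.frame(
        size = k, measures = labels[j], logL = res_logL[j], bic = res_bic[j],
        converged = res_conv[j], separated = res_sep[j], stringsAsFactors = FALSE)
      coefs[[length(coefs) + 1L]] <- f$coefficients
    }
  }
  models <- do.call(rbind, rows)
  rownames(models) <- NULL

  models$auc <- NA_real_; models$auc_lo <- NA_real_; models$auc_hi <- NA_real_
  for (i in seq_len(nrow(models))) {
    meas <- strsplit(models$measures[i], " \\+ ")[[1]]
    eta <- drop(cbind(1, xs[, meas, drop = FALSE]) %*% coefs[[i]])
    models$auc[i] <- empirical_auc(eta, y)
    if (n_boot > 0) {
      ci <- auc_ci(eta, y, n_boot = n_boot, seed = seed + i)
      models$auc_lo[i] <- ci$lower; models$auc_hi[i] <- ci$upper
    }
  }

  top <- rank_models(models, top = top_auc)
  models$rank <- NA_integer_
  models$rank[top] <- seq_along(top)

  sel <- table(unlist(strsplit(models$measures[top], " \\+ ")))
  sel <- sort(sel, decreasing = TRUE)

  structure(list(models = models, coefficients = coefs, top = top,
                 selection_freq = sel, n = n, dropped = dropped,
                 sizes = sizes, top_per_size = top_per_size, top_auc = top_auc,
                 scale = list(center = ctr, scale = scl),
                 x = x, y = y, call = match.call()),
            class = "fall_screen")
}

#' Rank candidate models by empirical AUC
#'
#' Sorts by descending AUC, breaking ties by ascending BIC and then
#' lexicographically on the measure names, and returns the indices of the top
#' models (at most `top`).
#'
#' @param models data.frame with columns `auc`, `bic`, `measures` (as produced
#'   by [best_subsets()]).
#' @param top how many models to return.
#' @return integer vector of row indices into `models`, best first.
#' @export
rank_models <- function(models, top = 10) {
  if (nrow(models) < 1) stop("no models to rank")
  ord <- order(-models$auc, models$bic, models$measures)
  utils::head(ord, top)
}

#' @export
print.fall_screen <- function(x, ...) {
  cat("Best-subsets logistic screen of gait measures\n")
  cat(sprintf("  subjects: %d (%d dropped for missingness), measures: %d\n",
              x$n, x$dropped, ncol(x$x)))
  cat(sprintf("  retained %d models (sizes %s, top %d per size by BIC)\n",
              nrow(x$models), paste(x$sizes, collapse = ", "), x$top_per_size))
  cat(sprintf("  top %d by empirical AUC:\n", length(x$top)))
  m <- x$models[x$top, ]
  for (i in seq_len(nrow(m))) {
    ci <- if (is.na(m$auc_lo[i])) "" else sprintf(" (%.2f-%.2f)", m$auc_lo[i], m$auc_hi[i])
    cat(sprintf("  %2d. AUC %.3f%s  BIC %6.2f  %s%s\n", i, m$auc[i], ci,
                m$bic[i], m$measures[i], if (m$separated[i]) "  [separated]" else ""))
  }
  invisible(x)
}

#' @export
summary.fall_screen <- function(object, ...) {
  out <- list(models = object$models[object$top, ],
              selection_freq = object$selection_freq,
              n = object$n, dropped = object$dropped)
  class(out) <- "summary.fall_screen"
  out
}

#' @export
print.summary.fall_screen <- function(x, ...) {
  cat("Top models by empirical AUC\n")
  print(x$models[, c("rank", "size", "measures", "bic", "auc", "auc_lo", "auc_hi")],
        row.names = FALSE, digits = 3)
  cat("\nMeasure selection frequency across the ranked models:\n")
  for (nm in names(x$selection_freq))
    cat(sprintf("  %s: %d of %d\n", nm, as.integer(x$selection_freq[[nm]]),
                nrow(x$models)))
  invisible(x)
}

#' @export
coef.fall_screen <- function(object, model = 1, ...) {
  object$coefficients[[object$top[model]]]
}

#' Predicted fall probabilities from a screened model
#'
#' @param object a `fall_screen`.
#' @param newdata data.frame with the measure columns used by the chosen model;
#'   defaults to the training measures.
#' @param model rank of the model to use (1 = best by AUC).
#' @param type `"response"` for probabilities, `"link"` for the linear score.
#' @param ... unused.
#' @export
predict.fall_screen <- function(object, newdata = NULL, model = 1,
                                type = c("response", "link"), ...) {
  type <- match.arg(type)
  i <- object$top[model]
  beta <- object$coefficients[[i]]
  meas <- strsplit(object$models$measures[i], " \\+ ")[[1]]
  if (is.null(newdata)) newdata <- object$x
  xm <- as.matrix(newdata[, meas, drop = FALSE])
  xm <- sweep(sweep(xm, 2, object$scale$center[meas]), 2, object$scale$scale[meas], "/")
  eta <- drop(cbind(1, xm) %*% beta)
  if (type == "link") eta else stats::plogis(eta)
}

#' ROC curves of the ranked models
#'
#' @param x a `fall_screen`.
#' @param models ranks of the models to draw (default: up to the first 4).
#' @param ... passed to [graphics::plot()].
#' @export
plot.fall_screen <- function(x, models = seq_len(min(4, length(x$top))), ...) {
  graphics::plot(c(0, 1), c(0, 1), type = "l", lty = 3, col = "grey",
                 xlab = "False positive rate", ylab = "True positive rate", ...)
  cols <- seq_along(models) + 1
  for (j in seq_along(models)) {
    eta <- predict(x, model = models[j], type = "link")
    roc <- roc_points(eta, x$y)
    graphics::lines(roc$fpr, roc$tpr, col = cols[j], lwd = 2)
  }
  lab <- sprintf("#%d AUC %.2f", models, x$models$auc[x$top[models]])
  graphics::legend("bottomright", legend = lab, col = cols, lwd = 2, bty = "n")
  invisible(x)
}

# Empirical ROC polygon vertices (thresholds at every distinct score).
roc_points <- function(scores, y) {
  y <- as.numeric(y)
  o <- order(scores, decreasing = TRUE)
  ys <- y[o]
  # group tied scores so the curve moves diagonally through ties
  g <- cumsum(!duplicated(scores[o]))
  tp <- tapply(ys, g, sum); fp <- tapply(1 - ys, g, sum)
  tpr <- c(0, cumsum(tp)) / sum(ys)
  fpr <- c(0, cumsum(fp)) / sum(1 - ys)
  list(fpr = unname(fpr), tpr = unname(tpr))
}

#' Two-group comparison with normality-based test routing
#'
#' Shapiro-Wilk normality at alpha 0.05 in each group routes continuous
#' variables to a two-sample t-test (both groups normal) or a Mann-Whitney U
#' test; categorical variables go to a chi-squared test. Groups too small for
#' the normality test (n < 3) fall back to Mann-Whitney.
#'
#' @param values vector of observations (numeric, or factor/character/logical
#'   for categorical data).
#' @param group two-level grouping vector.
#' @param type `"auto"` detects categorical input from the value class or from
#'   binary 0/1 coding; otherwise force `"continuous"` or `"categorical"`.
#' @return list with `test`, `statistic`, `p.value`, `shapiro_p` (per group,
#'   when computed).
#' @export
compare_groups <- function(values, group, type = c("auto", "continuous", "categorical")) {
  type <- match.arg(type)
  group <- as.factor(group)
  if (nlevels(group) != 2) stop("exactly two groups required")
  categorical <- switch(type,
    auto = is.factor(values) || is.character(values) || is.logical(values) ||
      all(values %in% c(0, 1)),
    continuous = FALSE,
    categorical = TRUE)
  if (categorical) {
    tab <- table(values, group)
    ct <- suppressWarnings(stats::chisq.test(tab))
    return(list(test = "chi-squared", statistic = unname(ct$statistic),
                p.value = ct$p.value, shapiro_p = NULL))
  }
  values <- as.numeric(values)
  sp <- vapply(levels(group), function(l) {
    v <- values[group == l]
    if (length(v) < 3 || length(unique(v)) < 2) NA_real_
    else stats::shapiro.test(v)$p.value
  }, numeric(1))
  if (all(!is.na(sp)) && all(sp > 0.05)) {
    tt <- stats::t.test(values ~ group)
    list(test = "t-test", statistic = unname(tt$statistic), p.value = tt$p.value,
         shapiro_p = sp)
  } else {
    wt <- suppressWarnings(stats::wilcox.test(values ~ group))
    list(test = "mann-whitney", statistic = unname(wt$statistic),
         p.value = wt$p.value, shapiro_p = sp)
  }
}

#' Sample size for a two-sample t-test at given power
#'
#' Smallest integer group size `n` at which a pooled-variance two-sample t-test
#' (pooled SD `sqrt((sd1^2 + sd2^2) / 2)`) attains the target power, computed
#' exactly from the noncentral-t distribution. The default sidedness is
#' one-sided, with a message so the choice is always visible.
#'
#' @param mean1,sd1 mean and SD of group 1.
#' @param mean2,sd2 mean and SD of group 2.
#' @param alpha significance level.
#' @param power target power.
#' @param sided `"one"` or `"two"`.
#' @param n_max search cap.
#' @return integer: subjects per group.
#' @examples
#' power_sample_size(0.59, 0.04, 0.54, 0.03) # 12
#' @export
power_sample_size <- function(mean1, sd1, mean2, sd2, alpha = 0.05, power = 0.95,
                              sided = c("one", "two"), n_max = 1e6) {
  sided <- match.arg(sided)
  if (sd1 <= 0 || sd2 <= 0) stop("SDs must be positive")
  if (alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1)
    stop("alpha and power must be in (0, 1)")
  if (mean1 == mean2) stop("effect size zero: group means are equal")
  if (sided == "one") message("power_sample_size: using a one-sided test")
  sp <- sqrt((sd1^2 + sd2^2) / 2)
  d <- abs(mean1 - mean2) / sp
  tails <- if (sided == "one") 1 else 2
  for (n in 2:n_max) {
    df <- 2 * n - 2
    ncp <- d * sqrt(n / 2)
    tcrit <- stats::qt(1 - alpha / tails, df)
    pw <- 1 - stats::pt(tcrit, df, ncp)
    if (tails == 2) pw <- pw + stats::pt(-tcrit, df, ncp)
    if (pw >= power) return(n)
  }
  stop("no n up to n_max attains the target power")
}
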