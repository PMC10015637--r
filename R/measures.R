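# The 52-measure digital gait catalog and its computation for a subject-week.

# Stride-table columns summarised by mean + SD, with domain and units.
STRIDE_QUANTITIES <- data.frame(
  quantity = c("cadence", "stride_time", "step_duration", "stance_pct",
               "swing_pct", "single_support_pct", "double_support_pct",
               "gait_speed", "stride_length", "elevation",
               "foot_strike_angle", "pitch_toe_off", "pitch_toe_off_max",
               "pitch_midswing", "toe_out", "lateral_excursion",
               "trunk_cor_rom", "trunk_sag_rom", "trunk_trans_rom",
               "trunk_cor_peak_vel", "trunk_sag_peak_vel", "trunk_trans_peak_vel"),
  domain = c(rep("LowerBody", 16), rep("LowerTrunk", 6)),
  units = c("steps/min", "s", "s", "%", "%", "%", "%", "m/s", "m", "m",
            "deg", "deg", "deg", "deg", "deg", "m",
            "deg", "deg", "deg", "deg/s", "deg/s", "deg/s"),
  stringsAsFactors = FALSE)

TURN_QUANTITIES <- data.frame(
  quantity = c("turn_angle", "turn_duration", "turn_peak_velocity",
               "steps_in_turn"),
  units = c("deg", "s", "deg/s", "count"),
  stringsAsFactors = FALSE)

#' The digital gait measure catalog
#'
#' The default catalog of 52 subject-week measures in four domains:
#' 16 Lower Body stride quantities summarised by their mean, 6 Lower Trunk
#' stride quantities summarised by their mean, 8 Turning measures (mean and
#' variability of turn angle, duration, peak velocity and steps per turn) and
#' 22 Variability measures (the stride-to-stride variability of the 16 Lower
#' Body and 6 Lower Trunk quantities). Stride quantities are pooled over all
#' straight-walking strides of both feet across the full monitoring week, with
#' equal weight per stride; turn quantities pool every detected turn.
#'
#' @param variability `"sd"` (sample standard deviation, the default) or
#'   `"cv"` (coefficient of variation) for the Variability-domain entries and
#'   the turning SDs.
#' @return data.frame with one row per measure: `name`, `domain`, `quantity`,
#'   `aggregation`, `units`.
#' @examples
#' nrow(measure_catalog())  # 52
#' @export
measure_catalog <- function(variability = c("sd", "cv")) {
  variability <- match.arg(variability)
  sq <- STRIDE_QUANTITIES
  vunits <- if (variability == "sd") sq$units else rep("ratio", nrow(sq))
  means <- data.frame(name = paste0(sq$quantity, "_mean"), domain = sq$domain,
                      quantity = sq$quantity, aggregation = "mean",
                      units = sq$units, stringsAsFactors = FALSE)
  vars <- data.frame(name = paste0(sq$quantity, "_", variability),
                     domain = "Variability", quantity = sq$quantity,
                     aggregation = variability, units = vunits,
                     stringsAsFactors = FALSE)
  tq <- TURN_QUANTITIES
  turn <- data.frame(
    name = c(paste0(tq$quantity, "_mean"), paste0(tq$quantity, "_", variability)),
    domain = "Turning",
    quantity = rep(tq$quantity, 2),
    aggregation = rep(c("mean", variability), each = nrow(tq)),
    units = c(tq$units, if (variability == "sd") tq$units else rep("ratio", nrow(tq))),
    stringsAsFactors = FALSE)
  out <- rbind(means, turn[seq_len(nrow(tq)), ], vars, turn[-seq_len(nrow(tq)), ])
  # order: LowerBody, LowerTrunk, Turning, Variability
  out <- out[order(match(out$domain, c("LowerBody", "LowerTrunk", "Turning",
                                       "Variability"))), ]
  rownames(out) <- NULL
  stopifnot(nrow(out) == 52L, !anyDuplicated(out$name))
  out
}

#' Reduce a subject-week of gait events to the measure catalog
#'
#' Pools all straight-walking strides of both feet over the monitoring week
#' (equal weight per stride) for the stride-derived entries, and all turns for
#' the turning entries. Mean entries are arithmetic means; variability entries
#' are sample standard deviations (or CVs, if the catalog was built that way).
#' Activity measures (days recorded, wear hours, bouts/strides/turns per hour)
#' are appended. If a subject has no straight strides the stride-derived
#' entries are `NA` and the vector is flagged; they are never reported as zero.
#'
#' @param strides stride event table (one row per stride; the schema produced
#'   by [segment_strides()] or by the ground-truth generator), including
#'   logical `straight`.
#' @param turns turn event table (one row per turn) or `NULL`.
#' @param bouts bout table (one row per gait bout) or `NULL`.
#' @param wear_hours total wear time across the week, hours (> 0).
#' @param catalog a [measure_catalog()].
#' @return one-row data.frame with one column per catalog entry plus
#'   `days_recorded`, `total_wear_hours`, `bouts_per_hour`, `strides_per_hour`,
#'   `turns_per_hour`, and a logical `missing_strides` flag.
#' @export
compute_subject_measures <- function(strides, turns, bouts, wear_hours,
                                     catalog = measure_catalog()) {
  if (is.null(wear_hours) || wear_hours <= 0) stop("wear_hours must be > 0")
  out <- stats::setNames(as.list(rep(NA_real_, nrow(catalog))), catalog$name)

  straight <- if (!is.null(strides) && nrow(strides))
    strides[strides$straight, , drop = FALSE] else NULL
  have_strides <- !is.null(straight) && nrow(straight) > 0

  agg <- function(x, how) {
    x <- x[is.finite(x)]
    if (!length(x)) return(NA_real_)
    switch(how,
           mean = mean(x),
           sd = stats::sd(x),
           cv = stats::sd(x) / abs(mean(x)))
  }

  for (i in seq_len(nrow(catalog))) {
    q <- catalog$quantity[i]
    how <- catalog$aggregation[i]
    if (q %in% STRIDE_QUANTITIES$quantity) {
      if (have_strides) out[[catalog$name[i]]] <- agg(straight[[q]], how)
    } else {
      if (!is.null(turns) && nrow(turns)) {
        v <- switch(q,
                    turn_angle = abs(turns$angle),
                    turn_duration = turns$duration,
                    turn_peak_velocity = turns$peak_velocity,
                    steps_in_turn = as.numeric(turns$n_steps_in))
        out[[catalog$name[i]]] <- agg(v, how)
      }
    }
  }

  out$days_recorded <- if (!is.null(strides) && nrow(strides))
    length(unique(strides$day)) else 0L
  out$total_wear_hours <- wear_hours
  out$bouts_per_hour <- (if (is.null(bouts)) 0 else nrow(bouts)) / wear_hours
  out$strides_per_hour <- (if (is.null(strides)) 0 else nrow(strides)) / wear_hours
  out$turns_per_hour <- (if (is.null(turns)) 0 else nrow(turns)) / wear_hours
  out$missing_strides <- !have_strides
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' Measure table for a whole cohort from ground-truth timelines
#'
#' Applies [compute_subject_measures()] to each subject of a synthetic cohort
#' using the ground-truth event tables (the exact-oracle path that bypasses
#' signal rendering and detection).
#'
#' @param cohort a `cohort` from [generate_cohort()].
#' @param catalog a [measure_catalog()].
#' @return data.frame, one row per subject, with `subject_id` first.
#' @export
cohort_measures <- function(cohort, catalog = measure_catalog()) {
  rows <- lapply(cohort$subjects, function(tr) {
    m <- compute_subject_measures(tr$strides, tr$turns, tr$bouts,
                                  tr$wear_hours, catalog)
    cbind(data.frame(subject_id = tr$subject_id, stringsAsFactors = FALSE), m)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
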