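# CSV interchange for streams, event tables and configuration.

#' Write an IMU stream to CSV
#'
#' Columns `time_s, ax, ay, az, gx, gy, gz`; numbers are written with 17
#' significant digits so a write/read round-trip reproduces the doubles
#' bit-identically. A JSON sidecar (`<path>.meta.json`) records the site, the
#' nominal sampling rate and the units.
#'
#' @param stream an [imu_stream()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_imu_csv <- function(stream, path) {
  if (!inherits(stream, "imu_stream")) stop("stream must be an imu_stream")
  df <- data.table::data.table(
    time_s = sprintf("%.17g", stream$time),
    ax = sprintf("%.17g", stream$accel[, 1]),
    ay = sprintf("%.17g", stream$accel[, 2]),
    az = sprintf("%.17g", stream$accel[, 3]),
    gx = sprintf("%.17g", stream$gyro[, 1]),
    gy = sprintf("%.17g", stream$gyro[, 2]),
    gz = sprintf("%.17g", stream$gyro[, 3]))
  data.table::fwrite(df, path, quote = FALSE)
  meta <- list(site = stream$site, fs = stream$fs,
               units = list(time_s = "s", accel = "m/s^2", gyro = "deg/s"))
  jsonlite::write_json(meta, paste0(path, ".meta.json"), auto_unbox = TRUE)
  invisible(path)
}

#' Read an IMU stream from CSV
#'
#' Validates the layout and the timestamps: non-numeric rows and non-monotone
#' timestamps are hard errors naming the offending data row; a sampling-rate
#' deviation of more than 5% from the declared rate is a warning.
#'
#' @param path CSV path written by [write_imu_csv()] (or matching its layout).
#' @param site sensor site; defaults to the sidecar value when present.
#' @param fs nominal sampling rate; defaults to the sidecar value, else 128.
#' @return an [imu_stream()].
#' @export
read_imu_csv <- function(path, site = NULL, fs = NULL) {
  meta_path <- paste0(path, ".meta.json")
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path)
    if (is.null(site)) site <- meta$site
    if (is.null(fs)) fs <- meta$fs
  }
  if (is.null(fs)) fs <- 128
  if (is.null(site)) stop("site not given and no metadata sidecar found")
  need <- c("time_s", "ax", "ay", "az", "gx", "gy", "gz")
  df <- data.table::fread(path, colClasses = list(numeric = intersect(
    need, names(data.table::fread(path, nrows = 0)))))
  if (!all(need %in% names(df)))
    stop("stream CSV must have columns ", paste(need, collapse = ", "))
  for (cc in need) {
    if (!is.numeric(df[[cc]]) || anyNA(df[[cc]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(as.character(df[[cc]])))))[1]
      stop(sprintf("malformed value in column '%s' at data row %d of %s",
                   cc, bad, path))
    }
  }
  dtm <- diff(df$time_s)
  if (any(dtm <= 0)) {
    bad <- which(dtm <= 0)[1]
    stop(sprintf("non-monotone timestamps at data row %d of %s", bad + 1L, path))
  }
  rate <- 1 / stats::median(dtm)
  if (abs(rate - fs) / fs > 0.05)
    warning(sprintf("observed sampling rate %.1f Hz deviates >5%% from the declared %g Hz",
                    rate, fs))
  imu_stream(site, df$time_s,
             as.matrix(df[, c("ax", "ay", "az")]),
             as.matrix(df[, c("gx", "gy", "gz")]), fs)
}

#' Write an event or measure table to CSV
#'
#' Plain full-precision CSV via [data.table::fwrite()].
#'
#' @param x data.frame.
#' @param path output path.
#' @export
write_table_csv <- function(x, path) {
  data.table::fwrite(x, path, quote = "auto")
  invisible(path)
}

#' Document the measure catalog as YAML
#'
#' @param catalog a [measure_catalog()].
#' @param path output path (`catalog.yaml`).
#' @export
write_catalog_yaml <- function(catalog, path) {
  entries <- lapply(seq_len(nrow(catalog)), function(i) list(
    name = catalog$name[i], domain = catalog$domain[i],
    quantity = catalog$quantity[i], aggregation = catalog$aggregation[i],
    units = catalog$units[i]))
  yaml::write_yaml(list(measures = entries), path)
  invisible(path)
}

#' Read a falls log CSV
#'
#' Expected columns: `subject_id`, `past_6mo_falls`, `period_start`,
#' `period_end`, `n_falls`, optionally `n_near_falls`.
#'
#' @param path CSV path.
#' @return data.frame suitable for [label_fallers()].
#' @export
read_falls_csv <- function(path) {
  df <- as.data.frame(data.table::fread(path))
  need <- c("subject_id", "past_6mo_falls", "period_start", "period_end", "n_falls")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("falls CSV is missing columns: ", paste(miss, collapse = ", "))
  df
}
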