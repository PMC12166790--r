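#' Write / read a raw recording as timestamped CSV
#'
#' The CSV has header `timestamp_iso8601,x_g,y_g,z_g`; the fixed sample rate
#' and start time are declared in a sidecar JSON (`<path>.json`) so readers
#' do not have to infer the rate from timestamps.
#'
#' @param raw A [raw_recording()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_raw_csv <- function(raw, path) {
  if (!inherits(raw, "raw_recording")) stop_input("`raw` must be a raw_recording")
  n <- nrow(raw$samples)
  ts <- raw$start_time + (seq_len(n) - 1) / raw$sample_rate_hz
  df <- data.frame(
    timestamp_iso8601 = format(ts, "%Y-%m-%dT%H:%M:%OS3%z"),
    x_g = raw$samples[, 1], y_g = raw$samples[, 2], z_g = raw$samples[, 3])
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  sidecar <- sprintf(
    '{"sample_rate_hz": %s, "start_time": "%s", "n_samples": %d}\n',
    format(raw$sample_rate_hz), format(raw$start_time, "%Y-%m-%dT%H:%M:%OS3%z"),
    n)
  cat(sidecar, file = paste0(path, ".json"))
  invisible(path)
}

#' @rdname write_raw_csv
#' @param sample_rate_hz Override for the sample rate; if `NULL` it is taken
#'   from the sidecar JSON, falling back to the median timestamp spacing.
#' @export
read_raw_csv <- function(path, sample_rate_hz = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("timestamp_iso8601", "x_g", "y_g", "z_g")
  if (!all(need %in% names(df)))
    stop_input("raw CSV needs columns %s", paste(need, collapse = ", "))
  start <- as.POSIXct(df$timestamp_iso8601[1], format = "%Y-%m-%dT%H:%M:%OS",
                      tz = "UTC")
  if (is.null(sample_rate_hz)) {
    sidecar <- paste0(path, ".json")
    if (file.exists(sidecar)) {
      txt <- paste(readLines(sidecar, warn = FALSE), collapse = "")
      m <- regmatches(txt, regexec('"sample_rate_hz"\\s*:\\s*([0-9.]+)', txt))[[1]]
      if (length(m) == 2) sample_rate_hz <- as.numeric(m[2])
    }
    if (is.null(sample_rate_hz)) {
      ts <- as.POSIXct(df$timestamp_iso8601, format = "%Y-%m-%dT%H:%M:%OS",
                       tz = "UTC")
      sample_rate_hz <- 1 / stats::median(diff(as.numeric(ts)))
    }
  }
  raw_recording(as.matrix(df[, c("x_g", "y_g", "z_g")]), sample_rate_hz, start)
}

#' Write / read longitudinal cohort tables as CSV
#'
#' The observation table is long format
#' (`participant_id,visit_months,outcome,value`); the survival table is
#' `participant_id,time_months,event,age_years,sex`.
#'
#' @param data An `mnd_longdata` object.
#' @param long_path,survival_path Output CSV paths.
#' @return The paths, invisibly.
#' @export
write_cohort_csv <- function(data, long_path, survival_path) {
  if (!inherits(data, "mnd_longdata")) stop_input("`data` must be mnd_longdata")
  utils::write.csv(data$long, long_path, row.names = FALSE)
  utils::write.csv(data$survival, survival_path, row.names = FALSE)
  invisible(c(long_path, survival_path))
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(long_path, survival_path) {
  longitudinal_dataset(utils::read.csv(long_path, stringsAsFactors = FALSE),
                       utils::read.csv(survival_path, stringsAsFactors = FALSE))
}
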