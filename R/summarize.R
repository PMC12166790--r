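#' Weekly accelerometer features with the 7-day trim-and-average protocol
#'
#' Implements the wear protocol summarisation: the first and last 12 h of the
#' recording are trimmed (devices are issued around midday and worn for 8
#' consecutive days, so trimming leaves exactly 7 x 24 h), the remainder is
#' partitioned into seven consecutive 24-h days aligned to the trimmed start,
#' each day is summarised (mean ENMO, MVPA minutes, peak 5-h ENMO, peak 6-min
#' activity, steps), and the weekly value of each feature is the unweighted
#' mean of the seven daily values.
#'
#' @param raw A [raw_recording()] spanning at least 8 days at >= 30 Hz.
#' @param enmo_epoch_s,counts_epoch_s Epoch lengths for the ENMO and counts
#'   series (defaults 5 s and 10 s).
#' @param mvpa_threshold_mg MVPA threshold in milli-g.
#' @param m5_window_hours Rolling peak-ENMO window (hours).
#' @param peak_window_minutes,peak_percentile Sliding-window peak-activity
#'   settings.
#' @return An object of class `weekly_features`: list with `daily` (7-row
#'   data.frame) and `weekly` (named numeric vector).
#' @export
summarize_recording <- function(raw, enmo_epoch_s = 5, counts_epoch_s = 10,
                                mvpa_threshold_mg = 100, m5_window_hours = 5,
                                peak_window_minutes = 6,
                                peak_percentile = 95) {
  if (!inherits(raw, "raw_recording")) stop_input("`raw` must be a raw_recording")
  fs <- raw$sample_rate_hz
  span_days <- nrow(raw$samples) / fs / 86400
  if (span_days < 8 - 1e-9)
    stop_input("recording spans %.2f days; the protocol needs at least 8",
               span_days)
  trim <- round(12 * 3600 * fs)
  keep <- seq(trim + 1, trim + round(7 * 86400 * fs))
  trimmed <- raw_recording(raw$samples[keep, , drop = FALSE], fs,
                           raw$start_time + 12 * 3600)

  enmo <- compute_enmo(trimmed, enmo_epoch_s)
  counts <- compute_activity_counts(trimmed, counts_epoch_s)
  per_day <- 86400 / enmo_epoch_s
  enmo_daily <- vapply(split_days(enmo), mean, numeric(1))
  mvpa <- mvpa_from_enmo(enmo, mvpa_threshold_mg)
  m5 <- rolling_peak_enmo(enmo, m5_window_hours)
  peak6 <- peak_window_percentile(counts, peak_window_minutes, peak_percentile)
  steps <- estimate_steps(trimmed)

  daily <- data.frame(
    day = 0:6,
    date = as.Date(trimmed$start_time) + 0:6,
    enmo_mean_mg = unname(enmo_daily[1:7]),
    mvpa_minutes = mvpa$mvpa_minutes[1:7],
    m5_enmo_mg = m5$m5[1:7],
    peak6_counts = peak6$peak[1:7],
    steps = steps$steps[1:7])
  weekly <- colMeans(daily[, c("enmo_mean_mg", "mvpa_minutes", "m5_enmo_mg",
                               "peak6_counts", "steps")])
  structure(list(daily = daily, weekly = weekly), class = "weekly_features")
}

#' @export
print.weekly_features <- function(x, ...) {
  cat("Weekly accelerometer features (mean of 7 trimmed days):\n")
  print(round(x$weekly, 2))
  invisible(x)
}

#' Select the fastest-declining epoch variant within each feature family
#'
#' Where a feature is computed at multiple epoch lengths, the analysis keeps
#' the variant whose standardised slope declines fastest (most negative
#' SD/month). Ties are broken deterministically by the shortest epoch.
#' Variants with a missing slope are excluded with a warning.
#'
#' @param candidates data.frame with columns `family`, `variant`, `epoch_s`,
#'   `std_slope`.
#' @return One row per family: the chosen variant.
#' @export
select_epoch_variant <- function(candidates) {
  req <- c("family", "variant", "epoch_s", "std_slope")
  if (!is.data.frame(candidates) || !all(req %in% names(candidates)))
    stop_input("`candidates` needs columns %s", paste(req, collapse = ", "))
  if (anyNA(candidates$std_slope)) {
    warning("excluding variants with missing standardised slope")
    candidates <- candidates[!is.na(candidates$std_slope), ]
  }
  if (nrow(candidates) == 0) stop_input("no candidate variants with slopes")
  picked <- lapply(split(candidates, candidates$family), function(d) {
    d <- d[order(d$std_slope, d$epoch_s), ]
    d[1, ]
  })
  out <- do.call(rbind, picked)
  rownames(out) <- NULL
  out
}
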