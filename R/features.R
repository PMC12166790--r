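#' Daily minutes of moderate-to-vigorous physical activity (MVPA)
#'
#' An epoch is "active" when its ENMO exceeds the threshold (strictly above,
#' default 100 milli-g on 5-s epochs). MVPA per day is the number of active
#' epochs times the epoch length in minutes. Days are consecutive 24-h blocks
#' aligned to the series start.
#'
#' @param enmo An [epoch_series()] of kind "enmo".
#' @param threshold_mg Activity threshold in milli-g.
#' @return data.frame with columns `day` (0-based) and `mvpa_minutes`.
#' @export
mvpa_from_enmo <- function(enmo, threshold_mg = 100) {
  if (!inherits(enmo, "epoch_series") || enmo$kind != "enmo")
    stop_input("`enmo` must be an epoch_series of kind 'enmo'")
  check_number(threshold_mg, "threshold_mg", min = 0)
  days <- split_days(enmo)
  data.frame(
    day = as.integer(names(days)),
    mvpa_minutes = vapply(days, function(v)
      sum(v > threshold_mg) * enmo$epoch_length_s / 60, numeric(1)),
    row.names = NULL)
}

# O(n) rolling mean over windows of k values, step one value.
rolling_mean <- function(v, k) {
  cs <- cumsum(c(0, v))
  (cs[(k + 1):length(cs)] - cs[1:(length(cs) - k)]) / k
}

#' Daily peak rolling-window mean ENMO (M5)
#'
#' For each day, the maximum over all within-day sliding windows (stepping
#' one epoch, never crossing day boundaries) of the window-mean ENMO. The
#' default 5-h window gives the "peak 5-h ENMO". Days shorter than one
#' window get `NA`.
#'
#' @param enmo An [epoch_series()] of kind "enmo".
#' @param window_hours Window length in hours.
#' @return data.frame with columns `day` and `m5` (milli-g).
#' @export
rolling_peak_enmo <- function(enmo, window_hours = 5) {
  if (!inherits(enmo, "epoch_series") || enmo$kind != "enmo")
    stop_input("`enmo` must be an epoch_series of kind 'enmo'")
  check_number(window_hours, "window_hours", min = 0, strict_min = TRUE)
  k <- window_hours * 3600 / enmo$epoch_length_s
  if (abs(k - round(k)) > 1e-9)
    stop_input("window must contain a whole number of epochs")
  k <- as.integer(round(k))
  days <- split_days(enmo)
  m5 <- vapply(days, function(v) {
    if (length(v) < k) return(NA_real_)
    max(rolling_mean(v, k))
  }, numeric(1))
  if (anyNA(m5))
    warning("some days are shorter than the window; M5 set to NA there")
  data.frame(day = as.integer(names(days)), m5 = m5, row.names = NULL)
}

#' Daily percentile of sliding-window activity ("peak" activity)
#'
#' Aggregates activity counts in every within-day sliding window (stepping
#' one epoch) and returns a per-day percentile of the window values. The
#' defaults — 6-minute windows, 95th percentile, window mean — give the
#' "peak 6-min activity" metric, a maximal sustained-output measure analogous
#' to the 95th-centile stride velocity endpoint. Percentiles use linear
#' interpolation between order statistics (R quantile type 7).
#'
#' @param counts An [epoch_series()] of kind "counts".
#' @param window_minutes Window length in minutes.
#' @param percentile Percentile in (0, 100].
#' @param aggregate Window aggregate: "mean" (default; units stay counts per
#'   epoch) or "sum".
#' @return data.frame with columns `day` and `peak`.
#' @export
peak_window_percentile <- function(counts, window_minutes = 6,
                                   percentile = 95,
                                   aggregate = c("mean", "sum")) {
  if (!inherits(counts, "epoch_series") || counts$kind != "counts")
    stop_input("`counts` must be an epoch_series of kind 'counts'")
  aggregate <- match.arg(aggregate)
  if (!is.numeric(percentile) || percentile <= 0 || percentile > 100)
    stop_input("`percentile` must be in (0, 100]")
  k <- window_minutes * 60 / counts$epoch_length_s
  if (abs(k - round(k)) > 1e-9)
    stop_input("window must contain a whole number of epochs")
  k <- as.integer(round(k))
  days <- split_days(counts)
  peak <- vapply(days, function(v) {
    if (length(v) < k) return(NA_real_)
    w <- rolling_mean(v, k)
    if (aggregate == "sum") w <- w * k
    unname(stats::quantile(w, percentile / 100, type = 7))
  }, numeric(1))
  if (anyNA(peak))
    warning("some days are shorter than the window; peak set to NA there")
  data.frame(day = as.integer(names(days)), peak = peak, row.names = NULL)
}
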