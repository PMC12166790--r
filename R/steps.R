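#' Wrist step counts by filtered peak detection (Verisense-style)
#'
#' Step detection on the acceleration vector magnitude, following the
#' published wrist step-count approach: the magnitude is block-averaged to
#' 15 Hz, candidate peaks are local maxima, and a candidate becomes a step
#' only if it passes four rule families with configurable parameters:
#' magnitude (peak height above `mag_thres` g), periodicity (gap to the
#' previous peak within `period_min..period_max` samples at 15 Hz, i.e.
#' 0.33-1 s for the defaults), similarity (height difference between
#' alternating peaks below `sim_delta` g), and continuity (at least
#' `cont_thres` consecutive rule-passing peaks, so isolated or aperiodic
#' peaks from noise are rejected). Steps are summed per recording-aligned
#' calendar day.
#'
#' @param raw A [raw_recording()] at >= 15 Hz.
#' @param mag_thres Minimum peak magnitude (g).
#' @param period_min,period_max Allowed inter-peak gap in 15 Hz samples.
#' @param sim_delta Maximum height difference between alternating peaks (g).
#' @param cont_thres Minimum run length of valid peaks counted as stepping.
#' @return data.frame with columns `day` and `steps`.
#' @export
estimate_steps <- function(raw, mag_thres = 1.2, period_min = 5,
                           period_max = 15, sim_delta = 0.5, cont_thres = 4) {
  if (!inherits(raw, "raw_recording")) stop_input("`raw` must be a raw_recording")
  fs <- raw$sample_rate_hz
  if (fs < 15) stop_input("step estimation requires a sample rate >= 15 Hz")
  mag <- sqrt(rowSums(raw$samples^2))
  # resample magnitude to 15 Hz by block means (non-integer ratios use
  # index binning)
  target <- 15
  if (fs %% target == 0) {
    dec <- fs %/% target
    nb <- length(mag) %/% dec
    mag15 <- colMeans(matrix(mag[seq_len(nb * dec)], nrow = dec))
  } else {
    n15 <- floor(length(mag) / fs * target)
    bin <- floor((seq_along(mag) - 1) / fs * target)
    mag15 <- as.numeric(tapply(mag, bin, mean))[seq_len(n15)]
  }

  n <- length(mag15)
  if (n < 3) return(data.frame(day = 0L, steps = 0))
  # candidate peaks: strict local maxima above the magnitude threshold
  is_peak <- c(FALSE, mag15[2:(n - 1)] > mag15[1:(n - 2)] &
                 mag15[2:(n - 1)] >= mag15[3:n], FALSE) & mag15 > mag_thres
  idx <- which(is_peak)
  steps_at <- integer(0)
  if (length(idx) >= cont_thres) {
    h <- mag15[idx]
    gap <- diff(idx)
    ok_period <- c(FALSE, gap >= period_min & gap <= period_max)
    ok_sim <- rep(TRUE, length(idx))
    if (length(idx) >= 3)
      ok_sim[3:length(idx)] <- abs(h[3:length(idx)] - h[1:(length(idx) - 2)]) <= sim_delta
    valid <- ok_period & ok_sim
    # continuity: keep runs of >= cont_thres consecutive valid peaks
    r <- rle(valid)
    keep <- rep(r$values & r$lengths >= cont_thres, r$lengths)
    steps_at <- idx[keep]
  }
  per_day <- 86400 * target
  n_days <- ceiling(n / per_day)
  steps <- tabulate(floor((steps_at - 1) / per_day) + 1L, nbins = n_days)
  data.frame(day = seq_len(n_days) - 1L, steps = steps, row.names = NULL)
}
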