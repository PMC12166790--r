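#' Construct a raw tri-axial accelerometer recording
#'
#' @param samples Numeric matrix with columns x, y, z, in g.
#' @param sample_rate_hz Sampling rate (Hz).
#' @param start_time POSIXct start of the recording.
#' @return An object of class `raw_recording`.
#' @export
raw_recording <- function(samples, sample_rate_hz,
                          start_time = as.POSIXct("2021-03-01 11:59:00",
                                                  tz = "UTC")) {
  samples <- as.matrix(samples)
  if (ncol(samples) != 3) stop_input("`samples` must have 3 columns (x, y, z)")
  if (nrow(samples) < 1) stop_input("empty recording")
  if (!all(is.finite(samples))) stop_input("samples must be finite")
  check_number(sample_rate_hz, "sample_rate_hz", min = 0, strict_min = TRUE)
  colnames(samples) <- c("x", "y", "z")
  structure(list(start_time = start_time, sample_rate_hz = sample_rate_hz,
                 samples = samples), class = "raw_recording")
}

#' Parameters for the raw wrist-signal generator
#'
#' The generated signal is gravity along `gravity_axis`, plus a bout-gated
#' sinusoidal arm-swing component along the same axis (so the swing modulates
#' the vector norm, as forearm movement does), plus white sensor noise. Bout
#' onsets follow a Poisson process whose rate, and whose swing amplitude,
#' scale with `activity_level`, the single dial that emulates a participant's
#' functional level.
#'
#' @param sample_rate_hz Sampling rate (Hz); devices record at 30.
#' @param duration_days Recording length in days; the wear protocol is 8.
#' @param activity_level Scalar in `[0, 1]` scaling bout rate and amplitude.
#' @param bout_rate_per_hour Poisson onset rate at `activity_level = 1`.
#' @param bout_duration_s_mean Mean bout duration (seconds, exponential,
#'   floored at 10 s).
#' @param swing_freq_hz Dominant arm-swing frequency (~2 Hz when walking).
#' @param swing_amplitude_g Peak swing amplitude at `activity_level = 1` (g).
#' @param noise_sd_g Sensor noise SD (g).
#' @param gravity_axis Unit orientation vector of gravity in the sensor frame.
#' @param start_time POSIXct start; the wear protocol starts at 11:59 AM.
#' @return An object of class `signal_params`.
#' @export
signal_params <- function(sample_rate_hz = 30, duration_days = 8,
                          activity_level = 0.5, bout_rate_per_hour = 10,
                          bout_duration_s_mean = 90, swing_freq_hz = 2,
                          swing_amplitude_g = 0.8, noise_sd_g = 0.01,
                          gravity_axis = c(0, 0, 1),
                          start_time = as.POSIXct("2021-03-01 11:59:00",
                                                  tz = "UTC")) {
  check_number(sample_rate_hz, "sample_rate_hz", min = 0, strict_min = TRUE)
  check_number(duration_days, "duration_days", min = 0, strict_min = TRUE)
  check_number(activity_level, "activity_level", min = 0, max = 1)
  check_number(bout_rate_per_hour, "bout_rate_per_hour", min = 0)
  check_number(swing_freq_hz, "swing_freq_hz", min = 0, strict_min = TRUE)
  check_number(noise_sd_g, "noise_sd_g", min = 0)
  if (length(gravity_axis) != 3 || abs(sqrt(sum(gravity_axis^2)) - 1) > 1e-8)
    stop_input("`gravity_axis` must be a 3-vector of unit norm")
  structure(list(sample_rate_hz = sample_rate_hz, duration_days = duration_days,
                 activity_level = activity_level,
                 bout_rate_per_hour = bout_rate_per_hour,
                 bout_duration_s_mean = bout_duration_s_mean,
                 swing_freq_hz = swing_freq_hz,
                 swing_amplitude_g = swing_amplitude_g,
                 noise_sd_g = noise_sd_g, gravity_axis = gravity_axis,
                 start_time = start_time), class = "signal_params")
}

#' Simulate a raw wrist accelerometer recording
#'
#' @param sp A [signal_params()] object.
#' @param seed Integer seed; identical seeds give identical recordings.
#' @return A [raw_recording()] with exactly
#'   `duration_days * 86400 * sample_rate_hz` samples.
#' @export
simulate_raw_recording <- function(sp, seed = 1L) {
  if (!inherits(sp, "signal_params")) stop_input("`sp` must be signal_params")
  with_seed(seed, {
    n <- round(sp$duration_days * 86400 * sp$sample_rate_hz)
    total_s <- sp$duration_days * 86400
    osc <- numeric(n)
    if (sp$activity_level > 0 && sp$bout_rate_per_hour > 0) {
      rate <- sp$bout_rate_per_hour * sp$activity_level
      n_bouts <- stats::rpois(1, rate * total_s / 3600)
      if (n_bouts > 0) {
        onset <- sort(stats::runif(n_bouts, 0, total_s))
        dur <- pmax(10, stats::rexp(n_bouts, 1 / sp$bout_duration_s_mean))
        amp <- sp$swing_amplitude_g * sp$activity_level *
          stats::runif(n_bouts, 0.8, 1.2)
        phase <- stats::runif(n_bouts, 0, 2 * pi)
        for (b in seq_len(n_bouts)) {
          i0 <- floor(onset[b] * sp$sample_rate_hz) + 1
          i1 <- min(n, floor((onset[b] + dur[b]) * sp$sample_rate_hz))
          if (i0 > n || i1 < i0) next
          tt <- (seq(i0, i1) - 1) / sp$sample_rate_hz
          osc[i0:i1] <- osc[i0:i1] +
            amp[b] * sin(2 * pi * sp$swing_freq_hz * tt + phase[b])
        }
      }
    }
    samples <- cbind(x = sp$gravity_axis[1] * (1 + osc),
                     y = sp$gravity_axis[2] * (1 + osc),
                     z = sp$gravity_axis[3] * (1 + osc))
    if (sp$noise_sd_g > 0)
      samples <- samples + matrix(stats::rnorm(3 * n, 0, sp$noise_sd_g), n, 3)
    raw_recording(samples, sp$sample_rate_hz, sp$start_time)
  })
}

#' @export
print.raw_recording <- function(x, ...) {
  n <- nrow(x$samples)
  cat(sprintf("Raw recording: %d samples at %g Hz (%.2f days), start %s\n",
              n, x$sample_rate_hz, n / x$sample_rate_hz / 86400,
              format(x$start_time, "%Y-%m-%d %H:%M:%S %Z")))
  invisible(x)
}
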