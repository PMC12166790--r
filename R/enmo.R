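#' Euclidean norm minus one (ENMO) per epoch
#'
#' Per sample, ENMO is `max(0, sqrt(x^2 + y^2 + z^2) - 1)` in g: the vector
#' magnitude of acceleration with the 1-g gravity contribution removed and
#' negatives truncated to zero. Samples are averaged within consecutive
#' epochs and reported in milli-g. A trailing partial epoch is dropped.
#'
#' @param raw A [raw_recording()].
#' @param epoch_length_s Epoch length in seconds; must contain a whole number
#'   of samples. The analysis default is 5 s.
#' @return An [epoch_series()] of kind "enmo" (milli-g).
#' @export
compute_enmo <- function(raw, epoch_length_s = 5) {
  if (!inherits(raw, "raw_recording")) stop_input("`raw` must be a raw_recording")
  spe <- epoch_length_s * raw$sample_rate_hz
  if (abs(spe - round(spe)) > 1e-9)
    stop_input("epoch_length_s * sample_rate_hz must be a whole number")
  spe <- as.integer(round(spe))
  n <- nrow(raw$samples)
  n_epochs <- n %/% spe
  if (n_epochs < 1) stop_input("recording shorter than one epoch")
  s <- raw$samples[seq_len(n_epochs * spe), , drop = FALSE]
  enmo <- pmax(0, sqrt(s[, 1]^2 + s[, 2]^2 + s[, 3]^2) - 1)
  means <- colMeans(matrix(enmo, nrow = spe))
  epoch_series(1000 * means, epoch_length_s, "enmo", raw$start_time)
}
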