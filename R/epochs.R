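#' Construct a per-epoch summary series
#'
#' Epochs are half-open intervals `[t, t + epoch_length_s)` with no gaps,
#' starting at `start_time`.
#'
#' @param values Per-epoch numeric values (ENMO in milli-g, or integer
#'   activity counts); all non-negative.
#' @param epoch_length_s Epoch length in seconds.
#' @param kind Either "enmo" or "counts".
#' @param start_time POSIXct start of the first epoch.
#' @return An object of class `epoch_series`.
#' @export
epoch_series <- function(values, epoch_length_s, kind = c("enmo", "counts"),
                         start_time = as.POSIXct("2021-03-01 11:59:00",
                                                 tz = "UTC")) {
  kind <- match.arg(kind)
  check_number(epoch_length_s, "epoch_length_s", min = 0, strict_min = TRUE)
  if (length(values) < 1) stop_input("empty epoch series")
  if (any(!is.finite(values)) || any(values < 0))
    stop_input("epoch values must be finite and >= 0")
  if (kind == "counts" && any(values != round(values)))
    stop_input("counts must be non-negative integers")
  structure(list(values = as.numeric(values), epoch_length_s = epoch_length_s,
                 kind = kind, start_time = start_time),
            class = "epoch_series")
}

# Split an epoch series into days. Days are consecutive 24-h blocks aligned
# to the series start ("recording-aligned"); a trailing partial day is kept
# and flagged by its epoch count.
split_days <- function(es) {
  per_day <- 86400 / es$epoch_length_s
  if (per_day != round(per_day))
    stop_input("epoch length must divide 86400 s for daily summaries")
  day <- floor((seq_along(es$values) - 1) / per_day)
  split(es$values, day)
}

#' @export
print.epoch_series <- function(x, ...) {
  cat(sprintf("Epoch series (%s): %d epochs of %g s, start %s\n", x$kind,
              length(x$values), x$epoch_length_s,
              format(x$start_time, "%Y-%m-%d %H:%M:%S %Z")))
  invisible(x)
}
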