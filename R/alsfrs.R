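#' Score the ALSFRS-R total and domains
#'
#' The revised ALS functional rating scale has 12 items scored 0-4 (total
#' 0-48). Domains: bulbar (items 1-3), upper-limb (items 4-5), lower-limb
#' (items 8-9), respiratory (items 10-12), and the combined motor domain
#' (items 4-9).
#'
#' @param items Integer vector of 12 item scores, or a matrix/data.frame with
#'   12 columns (one row per assessment).
#' @return data.frame with columns `total`, `bulbar`, `upper_limb`,
#'   `lower_limb`, `motor`, `respiratory` (one row per assessment).
#' @export
score_alsfrs <- function(items) {
  m <- if (is.null(dim(items))) matrix(items, nrow = 1) else as.matrix(items)
  if (ncol(m) != 12) stop_input("ALSFRS-R needs 12 item scores")
  if (any(!is.finite(m)) || any(m != round(m)) || any(m < 0) || any(m > 4))
    stop_input("items must be integers in [0, 4]")
  data.frame(total = rowSums(m),
             bulbar = rowSums(m[, 1:3, drop = FALSE]),
             upper_limb = rowSums(m[, 4:5, drop = FALSE]),
             lower_limb = rowSums(m[, 8:9, drop = FALSE]),
             motor = rowSums(m[, 4:9, drop = FALSE]),
             respiratory = rowSums(m[, 10:12, drop = FALSE]))
}

#' Pre-baseline progression rate (Delta FRS)
#'
#' `delta_frs = (ALSFRS-R total - 48) / months since symptom onset`: the
#' average monthly decline from the full score of 48, a standard prognostic
#' marker. A value of -0.5 per month is the conventional fast/slow
#' progression threshold.
#'
#' @param total ALSFRS-R total score(s), 0-48.
#' @param months_since_onset Months since symptom onset (> 0).
#' @return Per-month slope(s), typically <= 0.
#' @export
delta_frs <- function(total, months_since_onset) {
  if (any(!is.finite(total)) || any(total < 0) || any(total > 48))
    stop_input("`total` must be in [0, 48]")
  if (any(!is.finite(months_since_onset)) || any(months_since_onset <= 0))
    stop_input("`months_since_onset` must be > 0")
  (total - 48) / months_since_onset
}
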