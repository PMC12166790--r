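#' Per-participant residual matrix across outcomes
#'
#' Builds the participants x outcomes matrix of time-detrended residual
#' summaries used by the correlation and PCA analyses. For each outcome the
#' fixed and participant-specific (random) time trends of a mixed-model fit
#' are removed from every observation; the default summary per participant is
#' the mean of these observation-level residuals (`type = "mean_residual"`).
#' `type = "random_slope"` instead returns the participant's random-slope
#' deviation from the population slope, an alternative notion of residual
#' longitudinal behaviour.
#'
#' @param fits Named list of `lmm_fit` or `joint_fit` objects (one per
#'   outcome); joint fits contribute their longitudinal sub-model.
#' @param type Residual summary per participant.
#' @return Numeric matrix, participants x outcomes; cells are `NA` where a
#'   participant has no observations for an outcome.
#' @export
residual_matrix <- function(fits, type = c("mean_residual", "random_slope")) {
  type <- match.arg(type)
  if (!is.list(fits) || length(fits) == 0) stop_input("`fits` must be a list")
  fits <- lapply(fits, function(f) {
    if (inherits(f, "joint_fit")) f <- f$lmm
    if (!inherits(f, "lmm_fit")) stop_input("fits must be lmm_fit/joint_fit")
    f
  })
  nms <- names(fits)
  if (is.null(nms)) nms <- vapply(fits, function(f) f$outcome, character(1))
  per_fit <- lapply(fits, function(f) {
    if (type == "random_slope")
      return(stats::setNames(f$ranef$slope - f$fixed_slope,
                             f$ranef$participant_id))
    re <- f$ranef
    idx <- match(f$data$participant_id, re$participant_id)
    pred <- re$intercept[idx] + re$slope[idx] * f$data$visit_months
    r <- f$data$value - pred
    vapply(split(r, f$data$participant_id), mean, numeric(1))
  })
  all_ids <- sort(unique(unlist(lapply(per_fit, names))))
  common <- Reduce(intersect, lapply(per_fit, names))
  if (length(common) == 0)
    stop_input("no participants shared across the fitted outcomes")
  m <- sapply(per_fit, function(v) v[all_ids])
  rownames(m) <- all_ids
  colnames(m) <- nms
  m
}
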