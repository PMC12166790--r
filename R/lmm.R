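#' Linear mixed model for an outcome's decline over time
#'
#' Fits `value ~ visit_months + (visit_months | participant_id)`: a fixed
#' intercept and per-month slope, with participant-varying random intercept
#' and slope (unstructured 2x2 covariance). Estimation is restricted ML by
#' default. Wald 95% confidence intervals are reported for the fixed effects,
#' and empirical-Bayes participant-level intercepts/slopes are returned for
#' downstream use (two-stage joint modelling, residual analyses).
#'
#' @param data An `mnd_longdata` object, or a data.frame with columns
#'   `participant_id`, `visit_months`, `value` (already restricted to one
#'   outcome).
#' @param outcome Outcome name to model (ignored if `data` is a plain
#'   data.frame with a `value` column and no `outcome` column).
#' @param reml Use restricted ML (default) or ML.
#' @return An object of class `lmm_fit`.
#' @export
fit_lmm <- function(data, outcome = NULL, reml = TRUE) {
  df <- extract_outcome_df(data, outcome)
  nv <- table(df$participant_id)
  if (length(nv) < 2 || sum(nv >= 2) < 2)
    stop_input("need >= 2 participants with >= 2 visits to estimate a slope")
  df$participant_id <- factor(df$participant_id)
  fit <- tryCatch(
    suppressMessages(suppressWarnings(
      lmerTest::lmer(value ~ visit_months + (visit_months | participant_id),
                     data = df, REML = reml,
                     control = lme4::lmerControl(calc.derivs = FALSE,
                                                 check.conv.singular = "ignore"))
    )),
    error = function(e) stop_input("mixed model failed: %s", conditionMessage(e)))
  fe <- lme4::fixef(fit)
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))
  z <- stats::qnorm(0.975)
  vc <- lme4::VarCorr(fit)$participant_id
  D <- matrix(as.numeric(vc[1:2, 1:2]), 2, 2,
              dimnames = list(c("intercept", "slope"), c("intercept", "slope")))
  cf <- stats::coef(fit)$participant_id
  ranef_df <- data.frame(participant_id = rownames(cf),
                         intercept = cf[, "(Intercept)"],
                         slope = cf[, "visit_months"],
                         stringsAsFactors = FALSE)
  conv <- length(fit@optinfo$conv$lme4$messages) == 0
  structure(list(
    outcome = if (is.null(outcome)) "value" else outcome,
    fixed_intercept = unname(fe[1]), fixed_slope = unname(fe[2]),
    se_intercept = se[1], se_slope = se[2],
    ci_intercept = unname(fe[1]) + c(-1, 1) * z * se[1],
    ci_slope = unname(fe[2]) + c(-1, 1) * z * se[2],
    ranef_cov = D, residual_sd = stats::sigma(fit),
    ranef = ranef_df, converged = conv,
    singular = lme4::isSingular(fit),
    loglik = as.numeric(stats::logLik(fit)), reml = reml,
    n_participants = nlevels(df$participant_id), n_obs = nrow(df),
    model = fit, data = df), class = "lmm_fit")
}

# Pull a one-outcome observation data.frame out of the accepted input shapes.
extract_outcome_df <- function(data, outcome) {
  if (inherits(data, "mnd_cohort")) data <- as_longitudinal_dataset(data)
  if (inherits(data, "mnd_longdata")) {
    if (is.null(outcome)) stop_input("`outcome` required for a dataset")
    long <- data$long
    df <- long[long$outcome == outcome,
               c("participant_id", "visit_months", "value")]
  } else if (is.data.frame(data)) {
    if (!is.null(outcome) && "outcome" %in% names(data))
      data <- data[data$outcome == outcome, ]
    df <- data[c("participant_id", "visit_months", "value")]
  } else stop_input("unsupported data type")
  df <- df[is.finite(df$value), ]
  if (nrow(df) == 0) stop_input("no observations for outcome '%s'", outcome)
  df
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat(sprintf("Linear mixed model for '%s' (%s, %d participants, %d obs)\n",
              x$outcome, if (x$reml) "REML" else "ML",
              x$n_participants, x$n_obs))
  cat(sprintf("  slope: %.4g per month [%.4g, %.4g]\n",
              x$fixed_slope, x$ci_slope[1], x$ci_slope[2]))
  cat(sprintf("  intercept: %.4g [%.4g, %.4g]; residual SD %.4g\n",
              x$fixed_intercept, x$ci_intercept[1], x$ci_intercept[2],
              x$residual_sd))
  if (x$singular) cat("  note: singular random-effect covariance\n")
  invisible(x)
}
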