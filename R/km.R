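#' Median split of a baseline measure
#'
#' Values less than or equal to the cohort median go to the "low" group;
#' ties at the median are assigned to "low" by convention.
#'
#' @param x Numeric values.
#' @return Factor with levels `low`, `high`.
#' @export
median_split <- function(x) {
  med <- stats::median(x, na.rm = TRUE)
  factor(ifelse(x <= med, "low", "high"), levels = c("low", "high"))
}

#' Fast/slow progression groups from Delta FRS
#'
#' Conventional threshold of -0.5 points/month; values exactly at -0.5 are
#' assigned to the faster-progressing group.
#'
#' @param dfrs Delta-FRS values (points/month).
#' @param threshold Cut point.
#' @return Factor with levels `faster`, `slower`.
#' @export
delta_frs_group <- function(dfrs, threshold = -0.5) {
  factor(ifelse(dfrs <= threshold, "faster", "slower"),
         levels = c("faster", "slower"))
}

#' Kaplan-Meier curves, log-rank test and univariate Cox HR for two groups
#'
#' Product-limit survival estimates per group with Greenwood standard errors
#' and log-scale 95% confidence bands, median survival with confidence
#' interval (reported absent when unattained because too few deaths occurred
#' in a subgroup), the two-group log-rank test, and the hazard ratio of the
#' second group level versus the first from a univariate Cox proportional
#' hazards model.
#'
#' @param survival data.frame with `time_months` and `event` columns (e.g.
#'   the survival table of an `mnd_longdata`).
#' @param group Factor of two levels, one per row of `survival`.
#' @return An object of class `km_result`: `survfit`, `median` table,
#'   `logrank_chisq`, `logrank_p`, `cox_hr` with CI.
#' @export
km_logrank <- function(survival, group) {
  need <- c("time_months", "event")
  if (!all(need %in% names(survival)))
    stop_input("`survival` needs columns %s", paste(need, collapse = ", "))
  group <- droplevels(factor(group))
  if (nlevels(group) != 2 || any(table(group) == 0))
    stop_input("`group` must define two non-empty groups")
  if (sum(survival$event) < 1) stop_input("need at least one observed event")
  d <- data.frame(time = survival$time_months, event = survival$event,
                  group = group)
  sf <- survival::survfit(survival::Surv(time, event) ~ group, data = d,
                          conf.type = "log")
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ group, data = d)
  lr_p <- stats::pchisq(sd_$chisq, df = 1, lower.tail = FALSE)
  cx <- survival::coxph(survival::Surv(time, event) ~ group, data = d)
  hr <- exp(stats::coef(cx))
  ci <- exp(stats::confint(cx))
  med <- summary(sf)$table
  med <- med[, c("records", "events", "median", "0.95LCL", "0.95UCL"),
             drop = FALSE]
  structure(list(survfit = sf, median = med,
                 logrank_chisq = unname(sd_$chisq), logrank_p = lr_p,
                 cox_hr = unname(hr), cox_ci = as.numeric(ci),
                 levels = levels(group)), class = "km_result")
}

#' @export
print.km_result <- function(x, ...) {
  cat("Kaplan-Meier comparison (", paste(x$levels, collapse = " vs "), ")\n",
      sep = "")
  print(round(x$median, 2))
  cat(sprintf("log-rank chi-square %.3f, p = %.4g\n",
              x$logrank_chisq, x$logrank_p))
  cat(sprintf("univariate Cox HR (%s vs %s): %.3f [%.3f, %.3f]\n",
              x$levels[2], x$levels[1], x$cox_hr, x$cox_ci[1], x$cox_ci[2]))
  invisible(x)
}
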