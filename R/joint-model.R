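#' Joint longitudinal-survival model with a Weibull baseline hazard
#'
#' Couples the linear mixed sub-model of [fit_lmm()] with a proportional
#' hazards survival sub-model
#' `h_i(t) = h0(t) exp(gamma_age * age_i + gamma_sex * female_i + alpha * m_i(t))`,
#' where `h0` is a Weibull hazard `(k/lambda) (t/lambda)^(k-1)` and `m_i(t)`
#' is the participant's current subject-specific linear predictor of the
#' outcome. `alpha` is the association coefficient: the log hazard ratio per
#' unit of the current outcome value. Administrative censoring is applied at
#' `censor_months` before fitting. Age enters centred at the cohort mean and
#' sex is coded female = 1.
#'
#' Two estimation routes are provided. `method = "two_stage"` plugs the
#' empirical-Bayes participant trajectories from a restricted-ML mixed model
#' into the survival likelihood (fast; standard errors for `alpha` ignore
#' the uncertainty of the plug-in trajectories and are approximate).
#' `method = "full_likelihood"` maximises the joint marginal likelihood,
#' integrating the random effects by Gauss-Hermite quadrature centred on the
#' empirical-Bayes modes (`gh_points` nodes per dimension); the cumulative
#' hazard is integrated by Gauss-Legendre quadrature on each subject's
#' follow-up interval.
#'
#' @param data An `mnd_longdata`, `mnd_cohort`, or one-outcome data.frame.
#' @param survival Survival table (`participant_id`, `time_months`, `event`,
#'   `age_years`, `sex`); taken from `data` when it is a dataset/cohort.
#' @param outcome Outcome name to model.
#' @param method "two_stage" or "full_likelihood".
#' @param alpha_fixed Optionally fix the association coefficient (e.g. 0 to
#'   decouple the sub-models) instead of estimating it.
#' @param censor_months Administrative censoring horizon (months).
#' @param gh_points Gauss-Hermite nodes per random-effect dimension.
#' @param gl_points Gauss-Legendre nodes for the cumulative hazard.
#' @return An object of class `joint_fit`.
#' @export
fit_joint_model <- function(data, survival = NULL, outcome = NULL,
                            method = c("two_stage", "full_likelihood"),
                            alpha_fixed = NULL, censor_months = 36,
                            gh_points = 9, gl_points = 15) {
  method <- match.arg(method)
  if (inherits(data, "mnd_cohort")) data <- as_longitudinal_dataset(data)
  if (is.null(survival)) {
    if (!inherits(data, "mnd_longdata"))
      stop_input("`survival` is required unless `data` is a dataset/cohort")
    survival <- data$survival
  }
  df <- extract_outcome_df(data, outcome)
  surv <- survival[survival$participant_id %in% df$participant_id, ]
  miss <- setdiff(unique(df$participant_id), surv$participant_id)
  if (length(miss) > 0)
    stop_input("no survival row for %d modelled participants", length(miss))
  # administrative censoring
  over <- surv$time_months > censor_months
  surv$event[over] <- 0
  surv$time_months[over] <- censor_months
  if (sum(surv$event) < 1)
    stop_input("survival sub-model needs at least one observed event")

  lmm <- fit_lmm(df, outcome = outcome,
                 reml = (method == "two_stage"))
  ids <- surv$participant_id
  agec <- surv$age_years - mean(surv$age_years)
  fem <- as.numeric(surv$sex == "female")
  Ti <- pmax(surv$time_months, 1e-6)
  di <- surv$event
  gl <- gauss_legendre(gl_points)
  sd_y <- stats::sd(df$value)

  if (method == "two_stage") {
    re <- lmm$ranef
    a_i <- re$intercept[match(ids, re$participant_id)]
    b_i <- re$slope[match(ids, re$participant_id)]
    est_alpha <- is.null(alpha_fixed)
    negll <- function(p) {
      k <- exp(p[1]); lam <- exp(p[2])
      eta <- p[3] * agec + p[4] * fem
      alpha <- if (est_alpha) p[5] else alpha_fixed
      lh <- log(k) - k * log(lam) + (k - 1) * log(Ti) + eta +
        alpha * (a_i + b_i * Ti)
      tq <- outer(Ti, gl$nodes)                       # n x q
      hz <- (k / lam) * (tq / lam)^(k - 1) *
        exp(eta + alpha * (a_i + b_i * tq))
      H <- Ti * as.numeric(hz %*% gl$weights)
      -sum(di * lh - H)
    }
    p0 <- c(log(1.2), log(mean(Ti) * 2), 0, 0, if (est_alpha) 0)
    opt <- stats::optim(p0, negll, method = "BFGS",
                        control = list(maxit = 500), hessian = TRUE)
    vc <- tryCatch(solve(opt$hessian), error = function(e) NULL)
    alpha <- if (est_alpha) opt$par[5] else alpha_fixed
    alpha_se <- if (est_alpha && !is.null(vc)) sqrt(vc[5, 5]) else NA_real_
    fit <- list(
      lmm = lmm, method = method,
      fixed_intercept = lmm$fixed_intercept, fixed_slope = lmm$fixed_slope,
      se_slope = lmm$se_slope, ci_slope = lmm$ci_slope,
      weibull_shape = exp(opt$par[1]), weibull_scale = exp(opt$par[2]),
      gamma_age = opt$par[3], gamma_sex = opt$par[4],
      alpha = alpha, alpha_se = alpha_se,
      loglik = lmm$loglik - opt$value, surv_loglik = -opt$value,
      vcov = vc, converged = opt$convergence == 0 && lmm$converged,
      outcome_sd = sd_y, outcome = lmm$outcome,
      n_participants = length(ids), n_events = sum(di))
  } else {
    fit <- fit_joint_full(df, lmm, ids, agec, fem, Ti, di, gl, gh_points,
                          alpha_fixed, sd_y)
  }
  fit$hazard_ratios <- tryCatch(
    hazard_ratios(structure(fit, class = "joint_fit"), sd_y),
    error = function(e) NULL)
  structure(fit, class = "joint_fit")
}

# Full marginal likelihood via Gauss-Hermite quadrature centred on the
# empirical-Bayes modes of an initial mixed-model fit.
fit_joint_full <- function(df, lmm0, ids, agec, fem, Ti, di, gl, gh_points,
                           alpha_fixed, sd_y) {
  n <- length(ids)
  gh <- gauss_hermite(gh_points)
  zg <- as.matrix(expand.grid(z1 = gh$nodes, z2 = gh$nodes))
  lwg <- as.numeric(outer(log(gh$weights), log(gh$weights), "+")) +
    rowSums(zg^2)                       # log w1 w2 exp(|z|^2)
  K <- nrow(zg)

  # per-subject quadrature centres/scales from the EB posterior
  re_obj <- lme4::ranef(lmm0$model, condVar = TRUE)$participant_id
  pv <- attr(re_obj, "postVar")
  mu <- as.matrix(re_obj)[match(ids, rownames(re_obj)), , drop = FALSE]
  nodes_b0 <- matrix(0, n, K); nodes_b1 <- matrix(0, n, K)
  log_jac <- numeric(n)
  for (i in seq_len(n)) {
    Si <- pv[, , match(ids[i], rownames(re_obj))]
    Li <- t(chol(Si + diag(1e-10, 2)))
    bz <- sqrt(2) * zg %*% t(Li)
    nodes_b0[i, ] <- mu[i, 1] + bz[, 1]
    nodes_b1[i, ] <- mu[i, 2] + bz[, 2]
    log_jac[i] <- log(2) + sum(log(diag(Li)))
  }

  ys <- split(df$value, factor(df$participant_id, levels = ids))
  ts <- split(df$visit_months, factor(df$participant_id, levels = ids))
  est_alpha <- is.null(alpha_fixed)

  negll <- function(p) {
    beta0 <- p[1]; beta1 <- p[2]; sig <- exp(p[3])
    L <- matrix(c(exp(p[4]), p[5], 0, exp(p[6])), 2, 2)
    D <- L %*% t(L)
    Dinv <- chol2inv(chol(D))
    ldD <- 2 * (p[4] + p[6])
    k <- exp(p[7]); lam <- exp(p[8])
    ga <- p[9]; gs <- p[10]
    alpha <- if (est_alpha) p[11] else alpha_fixed
    eta <- ga * agec + gs * fem
    ll <- 0
    for (i in seq_len(n)) {
      b0 <- nodes_b0[i, ]; b1 <- nodes_b1[i, ]
      a_tot <- beta0 + b0; b_tot <- beta1 + b1
      # longitudinal density
      ll_long <- numeric(K)
      yi <- ys[[i]]; ti <- ts[[i]]
      if (length(yi) > 0) {
        resid <- outer(yi, rep(1, K)) - outer(rep(1, length(yi)), a_tot) -
          outer(ti, b_tot)
        ll_long <- -0.5 * colSums(resid^2) / sig^2 -
          length(yi) * (log(sig) + 0.5 * log(2 * pi))
      }
      # survival density
      m_T <- a_tot + b_tot * Ti[i]
      lh <- log(k) - k * log(lam) + (k - 1) * log(Ti[i]) + eta[i] + alpha * m_T
      tq <- Ti[i] * gl$nodes
      base_h <- (k / lam) * (tq / lam)^(k - 1)
      lp <- alpha * (outer(a_tot, rep(1, length(tq))) + outer(b_tot, tq))
      hz <- exp(eta[i] + lp) * matrix(base_h, K, length(tq), byrow = TRUE)
      H <- Ti[i] * as.numeric(hz %*% gl$weights)
      ll_surv <- di[i] * lh - H
      # random-effect prior
      qf <- b0^2 * Dinv[1, 1] + 2 * b0 * b1 * Dinv[1, 2] + b1^2 * Dinv[2, 2]
      ll_prior <- -0.5 * (qf + ldD) - log(2 * pi)
      ll <- ll + log_sum_exp(lwg + log_jac[i] + ll_long + ll_surv + ll_prior)
    }
    -ll
  }

  D0 <- lmm0$ranef_cov + diag(1e-6, 2)
  L0 <- t(chol(D0))
  p0 <- c(lmm0$fixed_intercept, lmm0$fixed_slope, log(lmm0$residual_sd),
          log(L0[1, 1]), L0[2, 1], log(L0[2, 2]),
          log(1.2), log(mean(Ti) * 2), 0, 0, if (est_alpha) 0)
  opt <- stats::nlminb(p0, negll, control = list(iter.max = 400))
  hess <- tryCatch(stats::optimHess(opt$par, negll), error = function(e) NULL)
  vc <- if (!is.null(hess))
    tryCatch(solve(hess), error = function(e) NULL) else NULL
  p <- opt$par
  se_all <- if (!is.null(vc)) sqrt(pmax(diag(vc), 0)) else rep(NA_real_, length(p))
  z <- stats::qnorm(0.975)
  L <- matrix(c(exp(p[4]), p[5], 0, exp(p[6])), 2, 2)
  alpha <- if (est_alpha) p[11] else alpha_fixed
  list(lmm = lmm0, method = "full_likelihood",
       fixed_intercept = p[1], fixed_slope = p[2],
       se_slope = se_all[2], ci_slope = p[2] + c(-1, 1) * z * se_all[2],
       residual_sd = exp(p[3]), ranef_cov = L %*% t(L),
       weibull_shape = exp(p[7]), weibull_scale = exp(p[8]),
       gamma_age = p[9], gamma_sex = p[10],
       alpha = alpha,
       alpha_se = if (est_alpha) se_all[11] else NA_real_,
       loglik = -opt$objective, vcov = vc,
       converged = opt$convergence == 0,
       outcome_sd = sd_y, outcome = lmm0$outcome,
       n_participants = n, n_events = sum(di))
}

#' Hazard-ratio scalings for a joint model's association coefficient
#'
#' Reports `exp(alpha)` on three scales: per base unit of the outcome, per
#' 100 units, and per pooled SD of the outcome, with Wald 95% confidence
#' intervals transformed identically. By construction the per-100 HR is the
#' base HR to the power 100 and the per-SD HR is the base HR to the power SD.
#'
#' @param fit A `joint_fit`.
#' @param outcome_sd SD used for the per-SD scaling (defaults to the pooled
#'   SD stored in the fit).
#' @return data.frame with columns `scaling`, `multiplier`, `hr`, `lower`,
#'   `upper`.
#' @export
hazard_ratios <- function(fit, outcome_sd = NULL) {
  if (!inherits(fit, "joint_fit")) stop_input("`fit` must be a joint_fit")
  if (is.null(outcome_sd)) outcome_sd <- fit$outcome_sd
  if (is.null(fit$alpha_se) || is.na(fit$alpha_se))
    stop_input("no standard error available for the association coefficient")
  z <- stats::qnorm(0.975)
  mult <- c(base = 1, per_100 = 100, per_sd = outcome_sd)
  data.frame(
    scaling = names(mult), multiplier = unname(mult),
    hr = exp(fit$alpha * mult),
    lower = exp((fit$alpha - z * fit$alpha_se) * mult),
    upper = exp((fit$alpha + z * fit$alpha_se) * mult),
    row.names = NULL)
}

#' @export
print.joint_fit <- function(x, ...) {
  cat(sprintf("Joint longitudinal-survival model for '%s' (%s)\n",
              x$outcome, x$method))
  cat(sprintf("  %d participants, %d events; Weibull shape %.3g, scale %.3g\n",
              x$n_participants, x$n_events, x$weibull_shape, x$weibull_scale))
  cat(sprintf("  slope: %.4g per month; association alpha = %.4g (SE %.3g)\n",
              x$fixed_slope, x$alpha, x$alpha_se))
  if (!is.null(x$hazard_ratios)) {
    cat("  hazard ratios:\n")
    print(cbind(x$hazard_ratios[1],
                round(x$hazard_ratios[c("hr", "lower", "upper")], 4)))
  }
  invisible(x)
}
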