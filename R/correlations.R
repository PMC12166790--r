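#' Holm step-down adjustment of p-values
#'
#' Step-down Holm correction: sort ascending, multiply the i-th smallest of m
#' p-values by `m - i + 1`, enforce monotonicity, cap at 1. Controls the
#' family-wise error rate without the independence assumptions of simpler
#' corrections. Delegates to [stats::p.adjust()].
#'
#' @param p Numeric vector of p-values in `[0, 1]` (`NA` allowed, returned
#'   as `NA`).
#' @return Adjusted p-values, same length and order.
#' @export
holm_adjust <- function(p) {
  if (!is.numeric(p)) stop_input("`p` must be numeric")
  px <- p[!is.na(p)]
  if (any(px < 0) || any(px > 1)) stop_input("p-values must be in [0, 1]")
  stats::p.adjust(p, method = "holm")
}

#' Pairwise outcome correlations, single-visit or residual-based
#'
#' Two procedures for correlating longitudinal outcomes while avoiding the
#' within-participant dependence of repeated measures:
#' `mode = "single_visit"` randomly selects one visit per participant
#' (seeded) and computes Pearson correlations across participants on those
#' single collections; `mode = "residual_partial"` computes Pearson
#' correlations between the columns of the per-participant residual matrix
#' from per-outcome mixed models (see [residual_matrix()]), i.e. correlations
#' with participant-level time trends partialled out — the longitudinal
#' residuals of a two-stage joint model are exactly these mixed-model
#' residuals. The two procedures answer slightly different questions and are
#' both provided. Holm adjustment is applied across all tested pairs as one
#' family; zero-variance outcomes are flagged and excluded from the family.
#'
#' @param data An `mnd_longdata` or `mnd_cohort`.
#' @param outcomes Outcome names to correlate (default: all in the data).
#' @param mode Correlation procedure.
#' @param seed Seed for the single-visit selection.
#' @param residual_type Passed to [residual_matrix()] in residual mode.
#' @return An object of class `correlation_result`: symmetric matrices `r`,
#'   `p`, `p_adj`, `n`, plus `mode` and any `excluded` outcomes.
#' @export
correlation_analysis <- function(data, outcomes = NULL,
                                 mode = c("single_visit", "residual_partial"),
                                 seed = 1L,
                                 residual_type = "mean_residual") {
  mode <- match.arg(mode)
  if (inherits(data, "mnd_cohort")) data <- as_longitudinal_dataset(data)
  if (!inherits(data, "mnd_longdata")) stop_input("`data` must be mnd_longdata")
  if (is.null(outcomes)) outcomes <- unique(data$long$outcome)
  if (length(outcomes) < 2) stop_input("need >= 2 outcomes")

  if (mode == "single_visit") {
    long <- data$long[data$long$outcome %in% outcomes, ]
    wide <- with_seed(seed, {
      picks <- lapply(split(long, long$participant_id), function(d) {
        vt <- unique(d$visit_months)
        v <- if (length(vt) == 1) vt else sample(vt, 1)
        d <- d[d$visit_months == v, ]
        vals <- stats::setNames(rep(NA_real_, length(outcomes)), outcomes)
        vals[d$outcome] <- d$value
        vals
      })
      do.call(rbind, picks)
    })
  } else {
    fits <- lapply(outcomes, function(o) fit_lmm(data, o))
    names(fits) <- outcomes
    wide <- residual_matrix(fits, type = residual_type)
  }
  if (nrow(wide) < 3) stop_input("need >= 3 participants with paired observations")

  sds <- apply(wide, 2, stats::sd, na.rm = TRUE)
  excluded <- colnames(wide)[is.na(sds) | sds == 0]
  keep <- setdiff(colnames(wide), excluded)
  if (length(excluded) > 0)
    warning("zero-variance outcome(s) excluded: ",
            paste(excluded, collapse = ", "))
  k <- length(keep)
  r <- p <- n <- matrix(NA_real_, k, k, dimnames = list(keep, keep))
  diag(r) <- 1; diag(p) <- 0
  diag(n) <- colSums(!is.na(wide[, keep, drop = FALSE]))
  pairs <- utils::combn(k, 2, simplify = FALSE)
  for (pr in pairs) {
    i <- pr[1]; j <- pr[2]
    ok <- stats::complete.cases(wide[, keep[c(i, j)]])
    n[i, j] <- n[j, i] <- sum(ok)
    if (sum(ok) >= 3) {
      ct <- stats::cor.test(wide[ok, keep[i]], wide[ok, keep[j]])
      r[i, j] <- r[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    }
  }
  raw <- vapply(pairs, function(pr) p[pr[1], pr[2]], numeric(1))
  adj <- holm_adjust(raw)
  p_adj <- matrix(NA_real_, k, k, dimnames = list(keep, keep))
  diag(p_adj) <- 0
  for (m in seq_along(pairs)) {
    i <- pairs[[m]][1]; j <- pairs[[m]][2]
    p_adj[i, j] <- p_adj[j, i] <- adj[m]
  }
  structure(list(r = r, p = p, p_adj = p_adj, n = n, mode = mode,
                 excluded = excluded), class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Pairwise Pearson correlations (%s mode):\n", x$mode))
  print(round(x$r, 3))
  cat("Holm-adjusted p-values:\n")
  print(signif(x$p_adj, 3))
  invisible(x)
}
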