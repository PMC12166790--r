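#' PCA on per-participant residuals
#'
#' Principal component analysis of the participants x outcomes residual
#' matrix (see [residual_matrix()]): columns are centred and scaled to unit
#' variance, so components are the eigenvectors of the correlation matrix —
#' appropriate because the outcomes have incommensurate units. The
#' contribution of variable j to component k is
#' `100 * loading_jk^2 / sum_j loading_jk^2`.
#'
#' @param residuals Numeric matrix (participants x outcomes), `NA` allowed.
#' @param missing How to handle missing cells: drop incomplete rows
#'   ("complete", default) or mean-impute ("mean_impute").
#' @return An object of class `pca_result`: orthonormal `loadings`,
#'   `variance_explained` fractions, `contributions` (percent, per
#'   component), `scores`, and `dropped` columns (zero variance).
#' @export
pca_residuals <- function(residuals, missing = c("complete", "mean_impute")) {
  missing <- match.arg(missing)
  m <- as.matrix(residuals)
  if (ncol(m) < 2 || nrow(m) < 3)
    stop_input("need >= 3 rows and >= 2 columns")
  all_na <- colSums(!is.na(m)) == 0
  if (any(all_na)) stop_input("column(s) entirely missing: %s",
                              paste(colnames(m)[all_na], collapse = ", "))
  if (missing == "mean_impute") {
    for (j in seq_len(ncol(m))) {
      mu <- mean(m[, j], na.rm = TRUE)
      m[is.na(m[, j]), j] <- mu
    }
  } else {
    m <- m[stats::complete.cases(m), , drop = FALSE]
    if (nrow(m) < 3) stop_input("fewer than 3 complete rows")
  }
  sds <- apply(m, 2, stats::sd)
  dropped <- colnames(m)[sds == 0]
  if (length(dropped) > 0) {
    warning("dropping zero-variance column(s): ",
            paste(dropped, collapse = ", "))
    m <- m[, sds > 0, drop = FALSE]
    if (ncol(m) < 2) stop_input("fewer than 2 informative columns remain")
  }
  pc <- stats::prcomp(m, center = TRUE, scale. = TRUE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  contrib <- 100 * sweep(pc$rotation^2, 2, colSums(pc$rotation^2), "/")
  structure(list(loadings = pc$rotation, variance_explained = ve,
                 contributions = contrib, scores = pc$x, sdev = pc$sdev,
                 dropped = dropped, n = nrow(m)), class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("PCA on residuals (%d participants, %d variables)\n",
              x$n, nrow(x$loadings)))
  cat("Variance explained:",
      paste(sprintf("PC%d %.1f%%", seq_along(x$variance_explained),
                    100 * x$variance_explained), collapse = ", "), "\n")
  cat("Contributions to PC1/PC2 (%):\n")
  print(round(x$contributions[, 1:min(2, ncol(x$contributions)), drop = FALSE], 1))
  invisible(x)
}
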