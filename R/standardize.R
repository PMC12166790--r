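#' Standardise an outcome to SD units
#'
#' Centres and scales all observations of an outcome to mean 0, SD 1 (sample
#' SD, denominator n-1, pooled over all observations), keeping the mean and
#' SD so the transformation can be inverted exactly. A slope in SD/month is
#' the absolute slope divided by the stored SD.
#'
#' @param x Numeric vector, or an `mnd_longdata` with `outcome` given.
#' @param outcome Outcome name when `x` is a dataset.
#' @return An object of class `standardized_outcome`: list with `values`,
#'   `mean`, `sd`.
#' @export
standardize_outcome <- function(x, outcome = NULL) {
  if (inherits(x, "mnd_longdata")) {
    if (is.null(outcome)) stop_input("`outcome` required for a dataset")
    x <- x$long$value[x$long$outcome == outcome]
  }
  x <- as.numeric(x)
  if (length(unique(x[is.finite(x)])) < 2)
    stop_input("need at least 2 distinct values to standardise")
  m <- mean(x, na.rm = TRUE)
  s <- stats::sd(x, na.rm = TRUE)
  if (s == 0) stop_input("zero variance; cannot standardise")
  structure(list(values = (x - m) / s, mean = m, sd = s),
            class = "standardized_outcome")
}

#' Invert a standardisation
#'
#' @param z A `standardized_outcome`, or numeric values on the SD scale.
#' @param ref The `standardized_outcome` carrying the mean/SD when `z` is
#'   numeric.
#' @return Values on the original scale.
#' @export
unstandardize <- function(z, ref = NULL) {
  if (inherits(z, "standardized_outcome"))
    return(z$values * z$sd + z$mean)
  if (!inherits(ref, "standardized_outcome"))
    stop_input("`ref` must be a standardized_outcome")
  z * ref$sd + ref$mean
}
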