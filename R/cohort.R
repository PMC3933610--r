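# Cohort-level association of computed indexes with a covariate (age).
# Distribution shape decides the correlation flavor: a Lilliefors-corrected
# Kolmogorov-Smirnov test (parameters estimated from the sample) gates
# Pearson vs Spearman, mirroring the usual normality-gated analysis chain.

#' Normality gate for the association stage
#'
#' TRUE when a Kolmogorov-Smirnov-family normality test (Lilliefors
#' correction, since mean and variance are estimated from the sample) fails
#' to reject Gaussianity at alpha = 0.05. Degenerate (constant) samples gate
#' to FALSE.
#'
#' @param values numeric vector, n >= 8.
#' @param alpha rejection level (default 0.05).
#' @return logical: TRUE means treat as Gaussian (use Pearson).
#' @export
normalityGate <- function(values, alpha = 0.05) {
  if (length(values) < 8L)
    .cvcStop("normality gate needs at least 8 values", "cvcInputError")
  if (sd(values) == 0) return(FALSE)
  nortest::lillie.test(values)$p.value >= alpha
}

#' Associate an index with a covariate across subjects
#'
#' Computes the correlation of an index with a covariate (age in the typical
#' design): Pearson product-moment when the index passes the normality gate,
#' Spearman rank-order otherwise, with a two-sided p-value and a
#' significance flag at alpha = 0.05.
#'
#' @param values per-subject index values.
#' @param covariate per-subject covariate (same length, n >= 8).
#' @param index name of the index (carried into the result).
#' @param alpha significance level (default 0.05).
#' @return one-row data.frame: \code{index}, \code{n}, \code{method}
#'   (\code{"pearson"}/\code{"spearman"}), \code{r}, \code{p},
#'   \code{significant}.
#' @export
associateIndex <- function(values, covariate, index = "index", alpha = 0.05) {
  keep <- is.finite(values) & is.finite(covariate)
  values <- values[keep]
  covariate <- covariate[keep]
  if (length(values) != length(covariate) || length(values) < 8L)
    .cvcStop("need at least 8 paired finite observations", "cvcInputError")
  if (sd(covariate) == 0)
    .cvcStop("constant covariate: association undefined", "cvcDegenerateError")
  if (sd(values) == 0)
    .cvcStop("constant index: association undefined", "cvcDegenerateError")
  method <- if (normalityGate(values, alpha)) "pearson" else "spearman"
  ct <- suppressWarnings(cor.test(values, covariate, method = method,
                                  exact = FALSE))
  data.frame(index = index, n = length(values), method = method,
             r = unname(ct$estimate), p = ct$p.value,
             significant = ct$p.value < alpha, stringsAsFactors = FALSE)
}
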