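#' Greedy forward selection minimizing conditional entropy
#'
#' Same construction strategy as \code{\link{forwardSelectLP}} (one lagged
#' component at a time, per-source pruning, run until the candidate set is
#' empty) but the figure of merit is the k-NN conditional entropy of the
#' effect, minimized. The CE profile typically falls while conditioning
#' helps and rises once the space becomes too sparse, so it attains a
#' minimum at the optimal dimension.
#'
#' @inheritParams forwardSelectLP
#' @param eps tolerance for the within-\code{eps} pair probability; defaults
#'   to 10 percent of the 84th-16th interpercentile range of the normalized
#'   effect series, computed once on the full window.
#' @return a \linkS4class{SelectionTrace} (method \code{"CE"}); the Shannon
#'   entropy of the effect is kept as the trace baseline.
#' @export
forwardSelectCE <- function(universe, spec, k = 30, theiler = NULL,
                            eps = NULL)
  .forwardSelect(universe, spec, k, theiler, "CE", eps = eps)

#' Conditional-entropy normalized complexity index
#'
#' \code{NCI = min(CE) / SE}, the minimal conditional entropy over the
#' selection trace normalized by the Shannon entropy of the effect, clipped
#' to [0, 1]: 0 means the universe removes all information from the effect
#' (null complexity), 1 means none (maximal complexity). When no addition
#' lowers CE below SE the optimal dimension is 0 and NCI = 1.
#'
#' @param trace a \linkS4class{SelectionTrace} from
#'   \code{\link{forwardSelectCE}}.
#' @return a \linkS4class{ComplexityResult} (method \code{"CE"}).
#' @export
nciCE <- function(trace) {
  stopifnot(trace@method == "CE")
  se <- trace@baseline
  if (se <= 0)
    .cvcStop("Shannon entropy of the effect is zero (constant series)",
             "cvcDegenerateError")
  minCE <- if (trace@optimalDim > 0) trace@criterion[trace@optimalDim] else se
  prof <- data.frame(dimension = seq_along(trace@criterion),
                     ce = trace@criterion)
  new("ComplexityResult", method = "CE", effect = trace@effect,
      nci = min(max(minCE / se, 0), 1), dimension = trace@optimalDim,
      profile = prof, components = selectedComponents(trace),
      details = list(shannon = se, eps = trace@eps, k = trace@k,
                     theiler = trace@theiler))
}

#' Conditional-entropy causality ratio
#'
#' \code{CR = (NCI_full - NCI_reduced) / NCI_reduced}, where the reduced NCI
#' re-evaluates the conditional entropy on the optimal selected set minus
#' the cause's components (no re-selection), normalized by the same Shannon
#' entropy. Exactly 0 when the optimal embedding holds no component of the
#' cause; CR < 0 reads as information transfer from the cause to the effect.
#'
#' @inheritParams forwardSelectCE
#' @param cause label of the candidate cause series.
#' @param trace optional precomputed \linkS4class{SelectionTrace} to reuse.
#' @param form \code{"fractional"} (default) or \code{"absolute"}.
#' @return a \linkS4class{CausalityResult}.
#' @export
crCE <- function(universe, spec, cause, k = 30, theiler = NULL, eps = NULL,
                 trace = NULL, form = c("fractional", "absolute")) {
  form <- match.arg(form)
  if (identical(cause, spec@effect))
    .cvcStop("cause must differ from the effect", "cvcSpecError")
  if (is.null(trace)) trace <- forwardSelectCE(universe, spec, k, theiler, eps)
  full <- nciCE(trace)
  sel <- selectedComponents(trace)
  hasCause <- any(sel$source == cause)
  nr <- NA_real_
  if (hasCause) {
    keep <- sel[sel$source != cause, , drop = FALSE]
    em <- fullEmbedding(universe, spec)
    ce <- if (nrow(keep) == 0L) trace@baseline else
      conditionalEntropy(subsetEmbedding(em, keep), k = trace@k,
                         theiler = trace@theiler, eps = trace@eps)
    nr <- min(max(ce / trace@baseline, 0), 1)
  }
  .mfCr("CE", spec@effect, cause, full@nci, nr, form, causeAbsent = !hasCause)
}
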