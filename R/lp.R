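#' Squared correlation between observed and predicted series
#'
#' Squared Pearson correlation, bounded in [0, 1]: 1 means perfect (possibly
#' sign-flipped) predictability, 0 none. A constant prediction carries no
#' predictive information and scores 0; a constant observed series has no
#' defined predictability and is rejected.
#'
#' @param observed numeric vector (length >= 3, non-constant).
#' @param predicted numeric vector of equal length.
#' @return r-squared in [0, 1].
#' @examples
#' rSquared(c(1, 2, 3, 4), c(1, 1, 2, 2))   # 0.8
#' @export
rSquared <- function(observed, predicted) {
  if (length(observed) != length(predicted) || length(observed) < 3L)
    .cvcStop("observed and predicted must be aligned, length >= 3",
             "cvcInputError")
  if (sd(observed) == 0)
    .cvcStop("observed series is constant", "cvcDegenerateError")
  if (sd(predicted) == 0) return(0)
  min(cor(observed, predicted)^2, 1)
}

# Shared greedy forward selection for the model-free estimators. At each
# step every remaining candidate is appended tentatively and scored by
# leave-self-out k-NN prediction (LP: r-squared, maximized) or k-NN
# conditional entropy (CE: minimized) over all rows; the best candidate is
# retained. Ties keep the earlier candidate in canonical order. After
# selecting (source s, lag l) every candidate of source s with lag <= l is
# pruned, so per-source lags strictly increase along the selection. The
# process runs until the candidate set is empty.
.forwardSelect <- function(universe, spec, k, theiler, method, eps = NULL) {
  em <- fullEmbedding(universe, spec)
  if (is.null(theiler)) theiler <- spec@p
  if (nrow(em@Z) - (2 * theiler + 1) < k)
    .cvcStop(sprintf(
      "window too short for k = %d neighbors with exclusion %d", k, theiler),
      "cvcDataError")
  y <- em@target
  comps <- em@components
  if (method == "CE") {
    if (is.null(eps)) eps <- epsTolerance(universe@data[, spec@effect])
    baseline <- shannonEntropy(y, eps)
  } else {
    eps <- NA_real_
    baseline <- 0
  }
  selected <- integer(0)
  crit <- numeric(0)
  remaining <- seq_len(nrow(comps))
  while (length(remaining)) {
    vals <- vapply(remaining, function(cand) {
      X <- em@Z[, c(selected, cand), drop = FALSE]
      if (method == "LP") {
        pred <- cpp_lp_predict(X, y, as.integer(k), as.integer(theiler))
        rSquared(y, pred)
      } else {
        cpp_ce_mean(X, y, as.integer(k), as.integer(theiler), eps)
      }
    }, numeric(1))
    bi <- if (method == "LP") which.max(vals) else which.min(vals)
    best <- remaining[bi]
    selected <- c(selected, best)
    crit <- c(crit, vals[bi])
    drop <- comps$source == comps$source[best] & comps$lag <= comps$lag[best]
    remaining <- setdiff(remaining[!drop[remaining]], selected)
  }
  sel <- comps[selected, , drop = FALSE]
  rownames(sel) <- NULL
  if (method == "LP") {
    optim <- if (length(crit) && max(crit) > baseline) which.max(crit) else 0L
  } else {
    optim <- if (length(crit) && min(crit) < baseline) which.min(crit) else 0L
  }
  new("SelectionTrace", method = method, effect = spec@effect,
      components = sel, criterion = crit, baseline = baseline,
      optimalDim = optim, k = k, theiler = theiler, eps = eps)
}

#' Greedy forward selection maximizing local predictability
#'
#' Grows the multivariate embedding one lagged component at a time, at each
#' step keeping the candidate whose addition maximizes the squared
#' correlation between the effect and its leave-self-out k-NN zero-order
#' prediction. The r-squared profile typically rises while components carry
#' information and falls once the space becomes too sparse for the k
#' neighbors, so it peaks at the optimal dimension.
#'
#' @param universe a normalized \linkS4class{BeatUniverse}.
#' @param spec an \linkS4class{EmbeddingSpec}.
#' @param k neighbor count (default 30).
#' @param theiler temporal exclusion half-width; defaults to the maximal lag
#'   \code{spec@p}.
#' @return a \linkS4class{SelectionTrace} (method \code{"LP"}).
#' @export
forwardSelectLP <- function(universe, spec, k = 30, theiler = NULL)
  .forwardSelect(universe, spec, k, theiler, "LP")

#' Local-predictability normalized complexity index
#'
#' \code{NCI = 1 - max(r-squared)} over the selection trace: 0 means perfect
#' predictability (null complexity), 1 full unpredictability. The optimal
#' dimension is the trace position of the maximum (0 when no component helps,
#' in which case NCI = 1).
#'
#' @param trace a \linkS4class{SelectionTrace} from
#'   \code{\link{forwardSelectLP}}.
#' @return a \linkS4class{ComplexityResult} (method \code{"LP"}).
#' @export
nciLP <- function(trace) {
  stopifnot(trace@method == "LP")
  best <- if (trace@optimalDim > 0) trace@criterion[trace@optimalDim] else 0
  prof <- data.frame(dimension = seq_along(trace@criterion),
                     r2 = trace@criterion)
  new("ComplexityResult", method = "LP", effect = trace@effect,
      nci = min(max(1 - best, 0), 1), dimension = trace@optimalDim,
      profile = prof, components = selectedComponents(trace),
      details = list(k = trace@k, theiler = trace@theiler))
}

# Shared causality-ratio arithmetic for the model-free estimators: both
# NCIs come from the optimal selected set, the reduced one from the same set
# minus the cause's components with no re-selection; the exact-zero rule
# applies when the optimal set holds no cause component.
.mfCr <- function(method, effect, cause, nciFull, nciReduced, form,
                  causeAbsent) {
  if (causeAbsent) {
    cr <- 0
    nciReduced <- nciFull
  } else if (form == "absolute") {
    cr <- nciFull - nciReduced
  } else {
    if (nciReduced <= 0)
      .cvcStop("reduced NCI is zero: causality ratio undefined",
               "cvcDegenerateError")
    cr <- (nciFull - nciReduced) / nciReduced
  }
  new("CausalityResult", method = method, effect = effect, cause = cause,
      cr = cr, nciFull = nciFull, nciReduced = nciReduced, form = form)
}

#' Local-predictability causality ratio
#'
#' \code{CR = (NCI_full - NCI_reduced) / NCI_reduced}, where the reduced NCI
#' re-runs the k-NN prediction on the optimal selected set with the cause's
#' components excluded (no re-selection). When the optimal embedding holds no
#' component of the cause, CR is exactly 0 (no causality); CR < 0 reads as
#' Granger causality from the cause to the effect.
#'
#' @inheritParams forwardSelectLP
#' @param cause label of the candidate cause series.
#' @param trace optional precomputed \linkS4class{SelectionTrace} to reuse
#'   (must match \code{spec}); run anew when NULL.
#' @param form \code{"fractional"} (default) or \code{"absolute"}.
#' @return a \linkS4class{CausalityResult}.
#' @export
crLP <- function(universe, spec, cause, k = 30, theiler = NULL, trace = NULL,
                 form = c("fractional", "absolute")) {
  form <- match.arg(form)
  if (identical(cause, spec@effect))
    .cvcStop("cause must differ from the effect", "cvcSpecError")
  if (is.null(trace)) trace <- forwardSelectLP(universe, spec, k, theiler)
  full <- nciLP(trace)
  sel <- selectedComponents(trace)
  hasCause <- any(sel$source == cause)
  nr <- NA_real_
  if (hasCause) {
    keep <- sel[sel$source != cause, , drop = FALSE]
    em <- fullEmbedding(universe, spec)
    r2 <- if (nrow(keep) == 0L) 0 else {
      X <- subsetEmbedding(em, keep)@Z
      pred <- cpp_lp_predict(X, em@target, as.integer(trace@k),
                             as.integer(trace@theiler))
      rSquared(em@target, pred)
    }
    nr <- min(max(1 - r2, 0), 1)
  }
  .mfCr("LP", spec@effect, cause, full@nci, nr, form, causeAbsent = !hasCause)
}
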