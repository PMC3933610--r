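# Linear model-based complexity and causality.
#
# The effect series is regressed (no intercept; series are zero-mean by
# construction) on the full candidate grid of lagged components at order p.
# The in-sample mean square prediction error lambda^2 of the unit-variance
# effect is the normalized complexity index once the order is chosen by the
# Akaike figure of merit; the causality ratio compares lambda^2 with and
# without the cause's columns at the same order and over the same rows.

.lambda2Floor <- 1e-12

.olsFit <- function(X, y) {
  if (ncol(X) == 0L)
    return(list(coef = numeric(0), lambda2 = mean(y^2)))
  fit <- lm.fit(X, y)
  if (any(is.na(fit$coefficients)))
    .cvcStop(sprintf(
      "rank-deficient regressor matrix (rank %d < %d, condition number %.3g)",
      fit$rank, ncol(X), kappa(X)), "cvcFitError")
  list(coef = stats::setNames(fit$coefficients, colnames(X)),
       lambda2 = mean(fit$residuals^2))
}

#' Fit the multivariate linear regression model at a given order
#'
#' Ordinary least squares of the effect on every candidate lagged component
#' at order \code{order} (per-source lags tau_j ... order). The residual
#' variance is the in-sample mean square prediction error over
#' n = order+1, ..., N.
#'
#' @param universe a normalized \linkS4class{BeatUniverse}.
#' @param spec an \linkS4class{EmbeddingSpec}; its \code{p} is replaced by
#'   \code{order}.
#' @param order model order p.
#' @return an \linkS4class{MvarFit}.
#' @export
fitMvar <- function(universe, spec, order = spec@p) {
  sp <- embeddingSpec(spec@effect, pmin(spec@tau, order), p = order)
  em <- fullEmbedding(universe, sp)
  if (nrow(em@Z) <= ncol(em@Z))
    .cvcStop(sprintf("underdetermined fit: %d rows for %d coefficients",
                     nrow(em@Z), ncol(em@Z)), "cvcDataError")
  f <- .olsFit(em@Z, em@target)
  new("MvarFit", coefficients = f$coef, lambda2 = f$lambda2, order = order,
      nEff = nrow(em@Z))
}

#' Select the model order by the Akaike figure of merit
#'
#' The in-sample residual variance is non-increasing in the order, so the
#' order is chosen at the minimum of
#' \code{AIC(p) = (N - p) * log(lambda^2(p)) + 2 * q(p)}, where q(p) is the
#' number of estimated coefficients. \code{lambda^2} is floored at 1e-12
#' before the log so noiseless inputs remain well-defined (a zero residual
#' wins immediately).
#'
#' @param universe a normalized \linkS4class{BeatUniverse}.
#' @param spec an \linkS4class{EmbeddingSpec}.
#' @param orders candidate orders (default 1:8).
#' @return list with \code{order} (the argmin) and \code{profile}
#'   (data.frame of order, coefficient count, lambda2, aic).
#' @export
akaikeOrder <- function(universe, spec, orders = 1:8) {
  prof <- lapply(orders, function(p) {
    f <- fitMvar(universe, spec, order = p)
    data.frame(order = p, q = length(f@coefficients), lambda2 = f@lambda2,
               aic = f@nEff * log(max(f@lambda2, .lambda2Floor)) +
                 2 * length(f@coefficients))
  })
  prof <- do.call(rbind, prof)
  list(order = prof$order[which.min(prof$aic)], profile = prof)
}

#' Model-based normalized complexity index
#'
#' NCI is the in-sample mean square prediction error of the normalized
#' effect series at the Akaike-optimal order, clipped to [0, 1]: 0 means the
#' effect is fully predictable in the universe (null complexity), 1 means it
#' is fully unpredictable (maximal complexity).
#'
#' @inheritParams akaikeOrder
#' @return a \linkS4class{ComplexityResult} (method \code{"MB"}); the raw
#'   residual variance and the Akaike profile are kept in \code{details} and
#'   \code{profile}.
#' @export
nciMB <- function(universe, spec, orders = 1:8) {
  sel <- akaikeOrder(universe, spec, orders = orders)
  l2 <- sel$profile$lambda2[sel$profile$order == sel$order]
  new("ComplexityResult", method = "MB", effect = spec@effect,
      nci = min(max(l2, 0), 1), dimension = sel$order,
      profile = sel$profile,
      components = candidateGrid(embeddingSpec(
        spec@effect, pmin(spec@tau, sel$order), p = sel$order)),
      details = list(lambda2 = l2, orders = orders))
}

#' Model-based causality ratio for one directed pair
#'
#' The causality ratio is the fractional unpredictability decrement of the
#' effect due to the inclusion of the cause:
#' \code{CR = (NCI_full - NCI_reduced) / NCI_reduced}, both indexes computed
#' at the order selected in the full universe and over the same target rows
#' (the reduced fit simply drops the cause's columns). Because the models are
#' nested in-sample, \code{CR <= 0} always; \code{CR < 0} reads as the cause
#' Granger-causing the effect in the universe.
#'
#' @inheritParams akaikeOrder
#' @param cause label of the candidate cause series (distinct from the
#'   effect).
#' @param form \code{"fractional"} (default) or \code{"absolute"}
#'   (\code{NCI_full - NCI_reduced}, not normalized).
#' @return a \linkS4class{CausalityResult}.
#' @export
crMB <- function(universe, spec, cause, orders = 1:8,
                 form = c("fractional", "absolute")) {
  form <- match.arg(form)
  if (identical(cause, spec@effect))
    .cvcStop("cause must differ from the effect", "cvcSpecError")
  if (!cause %in% names(spec@tau))
    .cvcStop(sprintf("cause %s is not a source of the spec", cause),
             "cvcSpecError")
  if (nSeries(universe) < 2L)
    .cvcStop("causality needs at least two series", "cvcSpecError")
  sel <- akaikeOrder(universe, spec, orders = orders)
  sp <- embeddingSpec(spec@effect, pmin(spec@tau, sel$order), p = sel$order)
  em <- fullEmbedding(universe, sp)
  keep <- which(em@components$source != cause)
  full <- .olsFit(em@Z, em@target)
  red <- .olsFit(em@Z[, keep, drop = FALSE], em@target)
  nf <- min(max(full$lambda2, 0), 1)
  nr <- min(max(red$lambda2, 0), 1)
  cr <- if (form == "absolute") nf - nr else {
    if (nr <= 0)
      .cvcStop("reduced-universe NCI is zero: causality ratio undefined",
               "cvcDegenerateError")
    (nf - nr) / nr
  }
  new("CausalityResult", method = "MB", effect = spec@effect, cause = cause,
      cr = cr, nciFull = nf, nciReduced = nr, form = form)
}
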