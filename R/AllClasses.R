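#' @import methods
#' @importFrom stats cor cor.test lm.fit quantile rnorm runif sd var
#' @importFrom utils read.delim write.table
#' @importFrom Rcpp evalCpp
#' @useDynLib cvcausal, .registration = TRUE
NULL

# Condition helpers: every user-facing failure carries a class so callers
# (and tests) can distinguish input, configuration, degenerate-input,
# specification, insufficient-data and fit errors.
.cvcStop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "cvcError", "error")))
}

.validUnits <- c("ms", "mmHg", "a.u.")

#' BeatSeries: one beat-indexed scalar series
#'
#' A single subject/condition series sampled once per cardiac beat, e.g. the
#' heart period (HP, ms), systolic arterial pressure (SAP, mmHg) or a per-beat
#' respiration sample (RESP, arbitrary units). Values are indexed by the
#' progressive beat counter n = 1, ..., N.
#'
#' @slot values numeric vector of beat-indexed measurements (finite, length
#'   at least 2).
#' @slot unit measurement unit, one of \code{"ms"}, \code{"mmHg"},
#'   \code{"a.u."}.
#' @slot label series identifier, e.g. \code{"HP"}.
#' @export
setClass("BeatSeries",
         slots = c(values = "numeric", unit = "character", label = "character"))

setValidity("BeatSeries", function(object) {
  if (length(object@values) < 2L)
    return("a beat series must hold at least 2 beats")
  if (!all(is.finite(object@values)))
    return("beat series values must all be finite")
  if (length(object@unit) != 1L || !object@unit %in% .validUnits)
    return(sprintf("unit must be one of %s", paste(.validUnits, collapse = ", ")))
  if (length(object@label) != 1L || !nzchar(object@label))
    return("label must be a non-empty string")
  TRUE
})

#' Construct a BeatSeries
#'
#' @param values numeric vector of per-beat measurements.
#' @param label series identifier (e.g. \code{"HP"}, \code{"SAP"},
#'   \code{"RESP"}).
#' @param unit measurement unit; defaults to the conventional unit of the
#'   label (ms for HP, mmHg for SAP, arbitrary units otherwise).
#' @return a \linkS4class{BeatSeries}.
#' @examples
#' hp <- beatSeries(c(800, 810, 805, 812), "HP")
#' seriesUnit(hp)
#' @export
beatSeries <- function(values, label, unit = NULL) {
  if (is.null(unit))
    unit <- switch(label, HP = "ms", SAP = "mmHg", "a.u.")
  new("BeatSeries", values = as.numeric(values), unit = unit, label = label)
}

#' BeatUniverse: the universe of jointly analyzed series
#'
#' An ordered collection of M beat series of common length N, stored as an
#' N x M matrix (columns are series). This is the universe of knowledge about
#' the system: every prediction/conditioning operation draws its candidate
#' components from it. After normalization each column has zero mean and unit
#' (population) variance.
#'
#' @slot data numeric N x M matrix, one column per series, colnames are the
#'   series labels.
#' @slot units character vector of per-series units.
#' @slot normalized logical flag; when TRUE each column has mean 0 and
#'   population variance 1 (within 1e-10).
#' @export
setClass("BeatUniverse",
         slots = c(data = "matrix", units = "character", normalized = "logical"))

setValidity("BeatUniverse", function(object) {
  d <- object@data
  if (!is.numeric(d) || is.null(colnames(d)))
    return("data must be a numeric matrix with column names (series labels)")
  if (nrow(d) < 2L) return("series must hold at least 2 beats")
  if (anyDuplicated(colnames(d))) return("series labels must be unique")
  if (!all(is.finite(d))) return("all values must be finite")
  if (length(object@units) != ncol(d))
    return("one unit per series is required")
  if (isTRUE(object@normalized)) {
    mu <- colMeans(d)
    v <- colMeans(sweep(d, 2L, mu)^2)
    if (any(abs(mu) > 1e-10) || any(abs(v - 1) > 1e-10))
      return("normalized universe must have zero-mean, unit-variance columns")
  }
  TRUE
})

#' Construct a BeatUniverse
#'
#' @param series a list of \linkS4class{BeatSeries} (all of equal length), or
#'   a numeric matrix with one named column per series.
#' @param units per-series units when \code{series} is a matrix.
#' @param normalized logical; declare the columns already normalized (checked
#'   by the validity method).
#' @return a \linkS4class{BeatUniverse}.
#' @examples
#' u <- beatUniverse(list(beatSeries(rnorm(64), "HP"),
#'                        beatSeries(rnorm(64), "SAP")))
#' nBeats(u); seriesLabels(u)
#' @export
beatUniverse <- function(series, units = NULL, normalized = FALSE) {
  if (is.list(series)) {
    lens <- vapply(series, function(s) length(s@values), integer(1))
    if (length(unique(lens)) != 1L)
      .cvcStop("all series in a universe must have the same length",
               "cvcInputError")
    d <- vapply(series, function(s) s@values, numeric(lens[1]))
    colnames(d) <- vapply(series, function(s) s@label, character(1))
    units <- vapply(series, function(s) s@unit, character(1))
  } else {
    d <- as.matrix(series)
    if (is.null(units)) units <- rep("a.u.", ncol(d))
  }
  new("BeatUniverse", data = d, units = units, normalized = isTRUE(normalized))
}

#' EmbeddingSpec: non-uniform embedding specification for one effect
#'
#' For a designated effect series i, the per-source minimum delays tau_j and
#' the common maximal lag p define the candidate grid of lagged components
#' (source j, lag tau_j ... p). The self delay must satisfy 1 <= tau_i <= p
#' (the effect never conditions on its own present value); cross delays may
#' be 0 to admit instantaneous, within-beat effects.
#'
#' @slot effect label of the effect series.
#' @slot tau named numeric vector of per-source minimum delays.
#' @slot p maximal lag (positive integer).
#' @export
setClass("EmbeddingSpec",
         slots = c(effect = "character", tau = "numeric", p = "numeric"))

setValidity("EmbeddingSpec", function(object) {
  if (length(object@effect) != 1L) return("exactly one effect label")
  if (is.null(names(object@tau)) || any(!nzchar(names(object@tau))))
    return("tau must be a named vector (one delay per source)")
  if (!object@effect %in% names(object@tau))
    return("tau must include the effect series itself")
  p <- object@p
  if (length(p) != 1L || p < 1 || p != round(p))
    return("p must be a positive integer")
  tau <- object@tau
  if (any(tau != round(tau)) || any(tau < 0))
    return("delays must be non-negative integers")
  if (tau[object@effect] < 1)
    return("the self delay must be at least 1")
  if (any(tau > p))
    return("every delay must satisfy tau <= p")
  TRUE
})

#' Construct an EmbeddingSpec
#'
#' @param effect label of the effect series.
#' @param tau named vector of per-source minimum delays; sources missing from
#'   \code{tau} are not part of the universe for this effect.
#' @param p maximal lag (default 8, the conventional short-term range).
#' @return an \linkS4class{EmbeddingSpec}.
#' @examples
#' embeddingSpec("HP", c(HP = 1, SAP = 0, RESP = 0), p = 8)
#' @export
embeddingSpec <- function(effect, tau, p = 8) {
  sp <- try(new("EmbeddingSpec", effect = effect,
                tau = stats::setNames(as.numeric(tau), names(tau)), p = p),
            silent = TRUE)
  if (inherits(sp, "try-error"))
    .cvcStop(attr(sp, "condition")$message, "cvcSpecError")
  sp
}

#' EmbeddingMatrix: realized multivariate embedding vectors
#'
#' Rows are the embedding vectors Z(n) for n = p+1, ..., N; the aligned
#' target vector holds the effect values y(n) for the same n. Columns follow
#' the canonical order: sources in universe order, lags ascending within a
#' source.
#'
#' @slot Z numeric matrix (N - p) x q of lagged components.
#' @slot target numeric vector of effect values aligned to the rows.
#' @slot components data.frame with columns \code{source}, \code{lag}
#'   describing the columns of \code{Z}.
#' @slot effect effect label.
#' @slot p maximal lag used to align rows.
#' @slot rows beat indices n of the rows (p+1, ..., N).
#' @export
setClass("EmbeddingMatrix",
         slots = c(Z = "matrix", target = "numeric", components = "data.frame",
                   effect = "character", p = "numeric", rows = "integer"))

setValidity("EmbeddingMatrix", function(object) {
  if (nrow(object@Z) != length(object@target))
    return("target must align with the rows of Z")
  if (ncol(object@Z) != nrow(object@components))
    return("one component descriptor per column required")
  TRUE
})

#' MvarFit: multivariate linear regression fit
#'
#' Ordinary least-squares fit of the effect on the full candidate grid at a
#' given order; the residual variance is the in-sample mean square prediction
#' error (population convention).
#'
#' @slot coefficients named coefficient vector over the candidate grid.
#' @slot lambda2 in-sample mean square prediction error.
#' @slot order model order p.
#' @slot nEff number of target samples used (N - p).
#' @export
setClass("MvarFit",
         slots = c(coefficients = "numeric", lambda2 = "numeric",
                   order = "numeric", nEff = "numeric"))

#' ComplexityResult: a normalized complexity index
#'
#' @slot method one of \code{"MB"}, \code{"LP"}, \code{"CE"}.
#' @slot effect effect series label.
#' @slot nci normalized complexity index in [0, 1].
#' @slot dimension optimal order (MB) or optimal embedding dimension (LP/CE).
#' @slot profile data.frame of the figure of merit versus order/dimension.
#' @slot components selected lagged components (LP/CE; empty for MB).
#' @slot details method-specific extras (e.g. raw residual variance,
#'   tolerance eps, Shannon entropy).
#' @export
setClass("ComplexityResult",
         slots = c(method = "character", effect = "character", nci = "numeric",
                   dimension = "numeric", profile = "data.frame",
                   components = "data.frame", details = "list"))

setValidity("ComplexityResult", function(object) {
  if (object@nci < 0 || object@nci > 1) return("nci must lie in [0, 1]")
  if (!object@method %in% c("MB", "LP", "CE")) return("unknown method tag")
  TRUE
})

#' CausalityResult: a causality ratio for one directed pair
#'
#' Negative values indicate that the cause carries unique information about
#' the future of the effect (Granger causality / information transfer).
#'
#' @slot method estimator tag.
#' @slot effect effect series label.
#' @slot cause cause series label.
#' @slot cr causality ratio.
#' @slot nciFull NCI in the full universe.
#' @slot nciReduced NCI in the reduced universe (cause excluded).
#' @slot form \code{"fractional"} (default) or \code{"absolute"}.
#' @export
setClass("CausalityResult",
         slots = c(method = "character", effect = "character",
                   cause = "character", cr = "numeric", nciFull = "numeric",
                   nciReduced = "numeric", form = "character"))

#' SelectionTrace: record of a greedy forward embedding selection
#'
#' @slot method \code{"LP"} or \code{"CE"}.
#' @slot effect effect series label.
#' @slot components data.frame (source, lag) in selection order.
#' @slot criterion figure of merit after each addition (r-squared for LP,
#'   conditional entropy for CE).
#' @slot baseline criterion of the empty embedding (0 for LP, the Shannon
#'   entropy of the effect for CE).
#' @slot optimalDim dimension at the criterion optimum (0 when the empty
#'   embedding is best).
#' @slot k neighbor count used.
#' @slot theiler temporal exclusion half-width used.
#' @slot eps tolerance used (CE only; NA for LP).
#' @export
setClass("SelectionTrace",
         slots = c(method = "character", effect = "character",
                   components = "data.frame", criterion = "numeric",
                   baseline = "numeric", optimalDim = "numeric",
                   k = "numeric", theiler = "numeric", eps = "numeric"))
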