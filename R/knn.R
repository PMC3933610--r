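#' Maximum-norm k-nearest-neighbor search with temporal exclusion
#'
#' Finds the k rows of \code{X} closest to row \code{query} under the
#' maximum norm (largest absolute componentwise difference), skipping rows
#' within the temporal exclusion half-width \code{theiler} of the query
#' (|m - n| <= theiler). Ties in distance are broken toward the smaller row
#' index. Distances are returned in ascending order.
#'
#' @param X numeric matrix; rows are embedding vectors ordered by beat index.
#' @param query row index of the query vector.
#' @param k neighbor count (default 30).
#' @param theiler exclusion half-width (default 0: only the query itself is
#'   excluded).
#' @return list with \code{index} (row indices) and \code{dist}.
#' @export
knnSearch <- function(X, query, k = 30, theiler = 0) {
  X <- as.matrix(X)
  adm <- sum(abs(seq_len(nrow(X)) - query) > theiler)
  if (adm < k)
    .cvcStop(sprintf("only %d admissible rows for k = %d", adm, k),
             "cvcDataError")
  cpp_knn_query(X, as.integer(query), as.integer(k), as.integer(theiler))
}

#' Inverse-distance weighted zero-order prediction
#'
#' Combines the images of a neighbor set into a locally constant prediction:
#' the weighted mean with weights 1/distance. Exact matches (distance 0)
#' dominate in the limit, so the prediction is then the unweighted mean of
#' the zero-distance images. The result always lies within the range of the
#' images.
#'
#' @param images target values of the neighbor rows.
#' @param dist neighbor distances (same length).
#' @return the predicted value.
#' @examples
#' zeroOrderPredict(c(2, 4), c(1, 3))   # 2.5
#' @export
zeroOrderPredict <- function(images, dist) {
  if (!length(images) || length(images) != length(dist))
    .cvcStop("images and dist must be non-empty and aligned", "cvcInputError")
  z <- dist == 0
  if (any(z)) return(mean(images[z]))
  w <- 1 / dist
  sum(w * images) / sum(w)
}

#' Probability that two samples lie within a tolerance
#'
#' Fraction of unordered distinct pairs of \code{values} whose absolute
#' difference is at most \code{eps} (closed inequality, self-pairs excluded).
#' Computed by a sort-and-count pass, so large vectors are fine.
#'
#' @param values numeric vector (length >= 2).
#' @param eps tolerance (>= 0).
#' @return probability in [0, 1].
#' @examples
#' pairWithinEps(c(0, 0.5, 2), 1)   # 1/3
#' @export
pairWithinEps <- function(values, eps) {
  n <- length(values)
  if (n < 2L) .cvcStop("need at least 2 values", "cvcInputError")
  v <- sort(values)
  within <- sum(findInterval(v + eps, v) - seq_len(n))
  within / (n * (n - 1) / 2)
}

#' Tolerance rule for the entropy estimators
#'
#' The tolerance is 10 percent of the difference between the 84th and 16th
#' percentiles of the effect series (roughly 2 SD for Gaussian data),
#' computed once on the full normalized window and reused for every
#' conditional sample.
#'
#' @param values the (normalized) effect series.
#' @return the tolerance eps.
#' @export
epsTolerance <- function(values) {
  q <- quantile(values, c(0.16, 0.84), names = FALSE, type = 7)
  0.1 * (q[2] - q[1])
}

#' Shannon entropy of a sample via within-tolerance pair probability
#'
#' The entropy of the (unconditioned) sample distribution is estimated as
#' the negative natural log of the probability that two samples lie within
#' \code{eps} of each other. A zero pair count is floored at one pair out of
#' n(n-1)/2 so the estimate stays finite. This is the q = 0 case of the
#' conditional-entropy estimator and its upper bound.
#'
#' @param values numeric vector (length >= 2).
#' @param eps tolerance; defaults to \code{\link{epsTolerance}(values)}.
#' @return entropy estimate >= 0.
#' @examples
#' shannonEntropy(c(0, 10, 20), eps = 1)   # -log(1/3), floored
#' @export
shannonEntropy <- function(values, eps = epsTolerance(values)) {
  p <- pairWithinEps(values, eps)
  n <- length(values)
  if (p <= 0) p <- 1 / (n * (n - 1) / 2)
  -log(p)
}

#' k-NN conditional entropy of a target given an embedding
#'
#' For every row n the conditional distribution of the target given Z(n) is
#' approximated by the images of the k nearest neighbors of Z(n) (maximum
#' norm, temporal exclusion); its Shannon entropy is the negative log of the
#' within-\code{eps} pair probability among those k images (floored at one
#' pair), and the conditional entropy is the average over rows. With an
#' empty embedding (zero columns) this reduces exactly to
#' \code{\link{shannonEntropy}} of the target.
#'
#' @param em an \linkS4class{EmbeddingMatrix} (possibly column-subset), or a
#'   plain numeric matrix.
#' @param target target values aligned to the rows (taken from \code{em}
#'   when it is an \linkS4class{EmbeddingMatrix}).
#' @param k neighbor count (default 30).
#' @param theiler temporal exclusion half-width; defaults to the embedding's
#'   maximal lag.
#' @param eps tolerance; defaults to \code{\link{epsTolerance}(target)}.
#' @return the conditional entropy estimate.
#' @export
conditionalEntropy <- function(em, target = NULL, k = 30, theiler = NULL,
                               eps = NULL) {
  if (is(em, "EmbeddingMatrix")) {
    Z <- em@Z
    if (is.null(target)) target <- em@target
    if (is.null(theiler)) theiler <- em@p
  } else {
    Z <- as.matrix(em)
    if (is.null(target)) .cvcStop("target required", "cvcInputError")
    if (is.null(theiler)) theiler <- 0
  }
  if (is.null(eps)) eps <- epsTolerance(target)
  if (ncol(Z) == 0L) return(shannonEntropy(target, eps))
  if (nrow(Z) - (2 * theiler + 1) < k)
    .cvcStop("not enough admissible rows for the neighbor search",
             "cvcDataError")
  cpp_ce_mean(Z, as.numeric(target), as.integer(k), as.integer(theiler), eps)
}
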