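#' Candidate grid of lagged components for an effect
#'
#' Enumerates every lagged component (source j, lag k) with
#' tau_j <= k <= p, in the canonical order: sources in universe order, lags
#' ascending within a source. The total count is q = sum_j (p - tau_j + 1).
#'
#' @param spec an \linkS4class{EmbeddingSpec}.
#' @param labels source labels in universe order; defaults to
#'   \code{names(spec@tau)}.
#' @return data.frame with columns \code{source}, \code{lag}.
#' @examples
#' sp <- embeddingSpec("HP", c(HP = 1, SAP = 0, RESP = 0), p = 8)
#' nrow(candidateGrid(sp))   # 8 + 9 + 9 = 26
#' @export
candidateGrid <- function(spec, labels = NULL) {
  validObject(spec)
  if (is.null(labels)) labels <- names(spec@tau)
  if (!all(labels %in% names(spec@tau)))
    .cvcStop("labels must all have a delay in the spec", "cvcSpecError")
  out <- do.call(rbind, lapply(labels, function(s) {
    lo <- spec@tau[[s]]
    data.frame(source = s, lag = seq.int(lo, spec@p),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Build the full multivariate embedding matrix
#'
#' Realizes the embedding vectors Z(n) over the complete candidate grid of
#' \code{spec} for n = p+1, ..., N, together with the aligned target vector
#' y(n) of the effect series. Dropping a source's columns yields the
#' reduced-universe embedding over the same target rows, so full/reduced
#' comparisons never differ in sample count.
#'
#' @param universe a normalized \linkS4class{BeatUniverse}.
#' @param spec an \linkS4class{EmbeddingSpec} whose sources are series of the
#'   universe.
#' @return an \linkS4class{EmbeddingMatrix}.
#' @export
fullEmbedding <- function(universe, spec) {
  validObject(spec)
  labels <- seriesLabels(universe)
  if (!spec@effect %in% labels)
    .cvcStop(sprintf("effect series %s not in universe", spec@effect),
             "cvcConfigError")
  miss <- setdiff(names(spec@tau), labels)
  if (length(miss))
    .cvcStop(sprintf("spec source(s) missing from the universe: %s",
                     paste(miss, collapse = ", ")), "cvcConfigError")
  src <- intersect(labels, names(spec@tau))
  N <- nBeats(universe)
  p <- as.integer(spec@p)
  if (N <= p)
    .cvcStop(sprintf("need more than p = %d beats, got %d", p, N),
             "cvcDataError")
  comps <- candidateGrid(spec, labels = src)
  rows <- (p + 1L):N
  Z <- matrix(0, length(rows), nrow(comps))
  for (c in seq_len(nrow(comps)))
    Z[, c] <- universe@data[rows - comps$lag[c], comps$source[c]]
  colnames(Z) <- sprintf("%s.l%d", comps$source, comps$lag)
  new("EmbeddingMatrix", Z = Z, target = universe@data[rows, spec@effect],
      components = comps, effect = spec@effect, p = spec@p, rows = rows)
}

#' Column-subset an embedding matrix
#'
#' Returns the embedding restricted to the requested lagged components, in
#' the requested order, with identical rows and target alignment. An empty
#' component list yields a legal zero-column embedding (the q = 0 state).
#'
#' @param em an \linkS4class{EmbeddingMatrix}.
#' @param components data.frame with \code{source}, \code{lag} columns, or an
#'   integer vector of column indices.
#' @return an \linkS4class{EmbeddingMatrix}.
#' @export
subsetEmbedding <- function(em, components) {
  if (is.numeric(components)) {
    idx <- as.integer(components)
    if (any(idx < 1L | idx > ncol(em@Z)))
      .cvcStop("component index out of range", "cvcSpecError")
  } else {
    key <- paste(em@components$source, em@components$lag)
    want <- paste(components$source, components$lag)
    idx <- match(want, key)
    if (anyNA(idx))
      .cvcStop(sprintf("unknown component(s): %s",
                       paste(want[is.na(idx)], collapse = ", ")),
               "cvcSpecError")
  }
  new("EmbeddingMatrix", Z = em@Z[, idx, drop = FALSE], target = em@target,
      components = em@components[idx, , drop = FALSE], effect = em@effect,
      p = em@p, rows = em@rows)
}
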