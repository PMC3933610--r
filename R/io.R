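#' Read beat-to-beat series from a delimited table
#'
#' Reads a TSV/CSV beat table (one row per cardiac beat, header line with
#' column names) and returns one \linkS4class{BeatSeries} per mapped column.
#' Any row holding a non-numeric entry in a mapped column aborts the read,
#' naming the offending data row.
#'
#' @param path path to the delimited file.
#' @param columns named character vector mapping series labels to column
#'   names, e.g. \code{c(HP = "hp_ms", SAP = "sap_mmhg")}; by default columns
#'   named HP, SAP, RESP are taken as-is.
#' @param sep field separator; \code{""} (default) autodetects tab vs comma
#'   from the header line.
#' @return a named list of \linkS4class{BeatSeries}, all of equal length.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeBeatTable(list(beatSeries(800 + rnorm(32), "HP"),
#'                     beatSeries(120 + rnorm(32), "SAP")), f)
#' s <- readBeatTable(f)
#' nBeats(s$HP)
#' @export
readBeatTable <- function(path, columns = NULL, sep = "") {
  if (!file.exists(path))
    .cvcStop(sprintf("file not found: %s", path), "cvcInputError")
  if (!nzchar(sep)) {
    hdr <- readLines(path, n = 1L)
    if (!length(hdr)) .cvcStop("empty file", "cvcInputError")
    sep <- if (grepl("\t", hdr)) "\t" else ","
  }
  raw <- read.delim(path, sep = sep, header = TRUE, colClasses = "character",
                    check.names = FALSE, strip.white = TRUE)
  if (nrow(raw) == 0L)
    .cvcStop("beat table holds a header but no data rows", "cvcInputError")
  if (is.null(columns)) {
    found <- intersect(c("HP", "SAP", "RESP"), names(raw))
    if (!length(found))
      .cvcStop("no HP/SAP/RESP columns found; pass an explicit column map",
               "cvcConfigError")
    columns <- stats::setNames(found, found)
  }
  missing <- setdiff(unname(columns), names(raw))
  if (length(missing))
    .cvcStop(sprintf("column(s) not present in %s: %s", path,
                     paste(missing, collapse = ", ")), "cvcConfigError")
  out <- vector("list", length(columns))
  names(out) <- names(columns)
  for (lab in names(columns)) {
    txt <- raw[[columns[[lab]]]]
    num <- suppressWarnings(as.numeric(txt))
    bad <- which(is.na(num) | !is.finite(num))
    if (length(bad))
      .cvcStop(sprintf("non-numeric value '%s' in column %s at data row %d",
                       txt[bad[1]], columns[[lab]], bad[1]), "cvcInputError")
    out[[lab]] <- beatSeries(num, lab)
  }
  out
}

#' Write beat series to a delimited table
#'
#' Inverse of \code{\link{readBeatTable}}: one column per series, one row per
#' beat, tab-separated with a header.
#'
#' @param series list of \linkS4class{BeatSeries} or a
#'   \linkS4class{BeatUniverse}.
#' @param path output path.
#' @param sep field separator (default tab).
#' @return \code{path}, invisibly.
#' @export
writeBeatTable <- function(series, path, sep = "\t") {
  if (is(series, "BeatUniverse")) {
    d <- series@data
  } else {
    d <- vapply(series, beatValues, numeric(nBeats(series[[1]])))
    colnames(d) <- vapply(series, seriesLabels, character(1))
  }
  write.table(d, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Normalize a series to zero mean and unit variance
#'
#' Uses the population variance convention (divide by N). Normalization is
#' idempotent; a constant series has no scale and is rejected.
#'
#' @param x numeric vector, \linkS4class{BeatSeries} or
#'   \linkS4class{BeatUniverse} (normalized column-wise).
#' @return an object of the same class as \code{x}.
#' @examples
#' normalizeSeries(c(1, 2, 3))   # -1.2247, 0, 1.2247
#' @export
setGeneric("normalizeSeries", function(x) standardGeneric("normalizeSeries"))

.normalizeNum <- function(v) {
  mu <- mean(v)
  s2 <- mean((v - mu)^2)
  if (s2 <= 0)
    .cvcStop("cannot normalize a constant series (zero variance)",
             "cvcDegenerateError")
  (v - mu) / sqrt(s2)
}

#' @rdname normalizeSeries
setMethod("normalizeSeries", "numeric", function(x) .normalizeNum(x))
#' @rdname normalizeSeries
setMethod("normalizeSeries", "BeatSeries", function(x) {
  initialize(x, values = .normalizeNum(x@values))
})
#' @rdname normalizeSeries
setMethod("normalizeSeries", "BeatUniverse", function(x) {
  d <- apply(x@data, 2L, .normalizeNum)
  colnames(d) <- colnames(x@data)
  initialize(x, data = d, normalized = TRUE)
})

#' Remove a least-squares linear trend over the beat index
#'
#' Fits y(n) = a + b n by ordinary least squares and returns the residuals.
#' The output is orthogonal to both the constant and the beat-index
#' regressor.
#'
#' @param x numeric vector, \linkS4class{BeatSeries} or
#'   \linkS4class{BeatUniverse} (detrended column-wise).
#' @return an object of the same class as \code{x}.
#' @export
setGeneric("linearDetrend", function(x) standardGeneric("linearDetrend"))

.detrendNum <- function(v) {
  if (length(v) < 2L)
    .cvcStop("need at least 2 beats to detrend", "cvcInputError")
  n <- seq_along(v)
  nc <- n - mean(n)
  b <- sum(nc * v) / sum(nc^2)
  a <- mean(v) - b * mean(n)
  v - (a + b * n)
}

#' @rdname linearDetrend
setMethod("linearDetrend", "numeric", function(x) .detrendNum(x))
#' @rdname linearDetrend
setMethod("linearDetrend", "BeatSeries", function(x)
  initialize(x, values = .detrendNum(x@values)))
#' @rdname linearDetrend
setMethod("linearDetrend", "BeatUniverse", function(x) {
  d <- apply(x@data, 2L, .detrendNum)
  colnames(d) <- colnames(x@data)
  initialize(x, data = d)
})

# Stationarity heuristic on one detrended window: split in halves and score
# the standardized mean difference against 0.5 pooled SD and the variance
# ratio against 2; a window passes when the worst score is <= 1. This
# automates the visual screen for slow mean drift or sudden variance change.
.stationarityScore <- function(v) {
  w <- .detrendNum(v)
  h <- length(w) %/% 2L
  a <- w[seq_len(h)]
  b <- w[(length(w) - h + 1L):length(w)]
  va <- mean((a - mean(a))^2)
  vb <- mean((b - mean(b))^2)
  pooled <- sqrt((va + vb) / 2)
  mscore <- if (pooled > 0) abs(mean(a) - mean(b)) / (0.5 * pooled) else
    as.numeric(abs(mean(a) - mean(b)) > 0)
  vscore <- if (min(va, vb) > 0) (max(va, vb) / min(va, vb)) / 2 else Inf
  max(mscore, vscore)
}

#' Randomly select an analysis window of consecutive beats
#'
#' Draws uniformly random admissible start indices until the candidate window
#' passes a stationarity heuristic (after linear detrending, the two window
#' halves must agree in mean within 0.5 pooled SD and in variance within a
#' factor 2), re-drawing up to \code{maxTries} times. If no candidate passes,
#' the best-scoring window is returned with a warning.
#'
#' @param series a list of \linkS4class{BeatSeries}/numeric vectors, a
#'   \linkS4class{BeatUniverse}, or a single numeric vector.
#' @param length window length in beats (default 256, the conventional
#'   short-term span).
#' @param seed optional integer seed for reproducible selection.
#' @param maxTries maximum number of redraws (default 100).
#' @return a list with \code{start} (1-based), \code{score} (heuristic score
#'   of the chosen window, <= 1 means pass), \code{passed} and \code{tries}.
#' @export
selectWindow <- function(series, length = 256, seed = NULL, maxTries = 100) {
  if (is(series, "BeatUniverse")) {
    mat <- series@data
  } else if (is.list(series)) {
    vals <- lapply(series, function(s)
      if (is(s, "BeatSeries")) s@values else as.numeric(s))
    if (length(unique(lengths(vals))) != 1L)
      .cvcStop("all series must have the same length", "cvcInputError")
    mat <- do.call(cbind, vals)
  } else {
    mat <- matrix(as.numeric(series), ncol = 1L)
  }
  N <- nrow(mat)
  if (N < length)
    .cvcStop(sprintf("series length %d shorter than window length %d",
                     N, length), "cvcInputError")
  if (N == length)
    return(list(start = 1L, score = max(apply(mat, 2L, .stationarityScore)),
                passed = NA, tries = 0L))
  if (!is.null(seed)) set.seed(seed)
  best <- NULL
  for (try in seq_len(maxTries)) {
    start <- sample.int(N - length + 1L, 1L)
    w <- mat[start:(start + length - 1L), , drop = FALSE]
    score <- max(apply(w, 2L, .stationarityScore))
    if (is.null(best) || score < best$score)
      best <- list(start = start, score = score, tries = try)
    if (score <= 1)
      return(list(start = start, score = score, passed = TRUE, tries = try))
  }
  warning(sprintf(
    "no window passed the stationarity heuristic in %d tries; returning best (score %.2f)",
    maxTries, best$score))
  list(start = best$start, score = best$score, passed = FALSE,
       tries = maxTries)
}

#' Window, detrend and normalize series into an analysis-ready universe
#'
#' Applies the per-subject preprocessing chain: select a window of
#' \code{windowLength} consecutive beats (stationarity-screened), linearly
#' detrend each series within the window, then normalize to zero mean and
#' unit variance. Normalization is performed within the selected window.
#'
#' @param series named list of \linkS4class{BeatSeries} (equal lengths).
#' @param windowLength window length in beats (default 256).
#' @param seed optional seed for the window draw.
#' @param maxTries redraw budget for the stationarity screen.
#' @return a list with \code{universe} (normalized
#'   \linkS4class{BeatUniverse}), \code{raw} (raw-unit windowed series, for
#'   threshold-based analyses such as the baroreflex sequence method) and
#'   \code{window} (the \code{\link{selectWindow}} record).
#' @export
prepareUniverse <- function(series, windowLength = 256, seed = NULL,
                            maxTries = 100) {
  win <- selectWindow(series, length = windowLength, seed = seed,
                      maxTries = maxTries)
  idx <- win$start:(win$start + windowLength - 1L)
  raw <- lapply(series, function(s) initialize(s, values = s@values[idx]))
  proc <- lapply(raw, function(s) normalizeSeries(linearDetrend(s)))
  list(universe = beatUniverse(proc, normalized = TRUE), raw = raw,
       window = win)
}
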