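# Per-subject orchestration and cohort aggregation. The defaults reproduce
# the conventional settings of the framework: orders 1..8 for the linear
# estimator, maximal lag 8 for the candidate grids, k = 30 neighbors,
# window length 256, within-beat (lag-0) fast pathways SAP->HP, RESP->HP
# and RESP->SAP, and one-beat delays for HP->SAP, HP->RESP and SAP->RESP.

#' Default embedding specifications for the HP/SAP/RESP universe
#'
#' One \linkS4class{EmbeddingSpec} per effect, encoding the physiological
#' delay conventions: the fast vagal reflex lets SAP and RESP act on HP
#' within the same beat (tau = 0); RESP acts on SAP within the beat through
#' intrathoracic pressure (tau = 0); HP cannot affect the SAP of the same
#' beat by measurement convention (tau = 1); HP and SAP act on RESP only
#' with delay (tau = 1). Self delays are always >= 1.
#'
#' @param p maximal lag (default 8).
#' @return named list of \linkS4class{EmbeddingSpec} for effects HP, SAP,
#'   RESP.
#' @export
cardioSpecs <- function(p = 8) {
  list(
    HP   = embeddingSpec("HP",   c(HP = 1, SAP = 0, RESP = 0), p = p),
    SAP  = embeddingSpec("SAP",  c(HP = 1, SAP = 1, RESP = 0), p = p),
    RESP = embeddingSpec("RESP", c(HP = 1, SAP = 1, RESP = 1), p = p))
}

#' Analyze one subject/condition recording
#'
#' Full per-subject chain: read (or accept) the HP/SAP/RESP beat series,
#' select a stationarity-screened window, compute traditional time-domain
#' indexes (mean and variance of HP and SAP, BRS, BEI) on the raw-unit
#' window, detrend and normalize, then compute the normalized complexity
#' index of each effect series and the causality ratio of each directed
#' pair for every requested method. Deterministic under a fixed seed.
#'
#' @param x path to a beat table, a named list of \linkS4class{BeatSeries},
#'   or a raw \linkS4class{BeatUniverse}.
#' @param methods subset of \code{c("MB", "LP", "CE")}.
#' @param windowLength analysis window in beats (default 256).
#' @param seed optional seed for the window draw.
#' @param orders candidate orders for the linear estimator (default 1:8).
#' @param k neighbor count for the model-free estimators (default 30).
#' @param theiler temporal exclusion half-width (default: the maximal lag).
#' @param p maximal lag of the candidate grids (default 8).
#' @param specs optional named list of \linkS4class{EmbeddingSpec} replacing
#'   \code{\link{cardioSpecs}} (labels must match the data).
#' @return list with \code{complexity} (data.frame effect x method),
#'   \code{causality} (data.frame pair x method), \code{baroreflex},
#'   \code{traditional}, \code{window} and \code{traces}.
#' @export
runSubject <- function(x, methods = c("MB", "LP", "CE"), windowLength = 256,
                       seed = NULL, orders = 1:8, k = 30, theiler = NULL,
                       p = 8, specs = NULL) {
  methods <- match.arg(methods, several.ok = TRUE)
  if (is.character(x)) x <- readBeatTable(x)
  if (is(x, "BeatUniverse"))
    x <- stats::setNames(lapply(seriesLabels(x), function(l)
      beatSeries(x@data[, l], l, unit = seriesUnit(x)[[l]])),
      seriesLabels(x))
  labels <- vapply(x, seriesLabels, character(1))
  names(x) <- labels
  if (is.null(specs)) {
    if (!all(c("HP", "SAP", "RESP") %in% labels))
      .cvcStop("default specs need HP, SAP and RESP series; pass `specs`",
               "cvcConfigError")
    specs <- cardioSpecs(p = p)
  }
  prep <- prepareUniverse(x, windowLength = windowLength, seed = seed)
  u <- prep$universe

  traditional <- do.call(rbind, lapply(intersect(c("HP", "SAP"), labels),
    function(l) {
      v <- beatValues(prep$raw[[l]])
      data.frame(series = l, mean = mean(v), variance = mean((v - mean(v))^2))
    }))
  baro <- if (all(c("HP", "SAP") %in% labels))
    baroreflexAnalysis(prep$raw$HP, prep$raw$SAP) else NULL

  cx <- list(); cs <- list(); traces <- list()
  for (eff in names(specs)) {
    sp <- specs[[eff]]
    others <- setdiff(names(sp@tau), eff)
    if ("MB" %in% methods) {
      res <- nciMB(u, sp, orders = orders)
      cx[[length(cx) + 1L]] <- data.frame(effect = eff, method = "MB",
                                          nci = res@nci,
                                          dimension = res@dimension)
      for (cause in others) {
        cr <- crMB(u, sp, cause, orders = orders)
        cs[[length(cs) + 1L]] <- data.frame(effect = eff, cause = cause,
                                            method = "MB", cr = cr@cr,
                                            nciFull = cr@nciFull,
                                            nciReduced = cr@nciReduced)
      }
      traces[[paste0(eff, ".MB")]] <- res@profile
    }
    if ("LP" %in% methods) {
      tr <- forwardSelectLP(u, sp, k = k, theiler = theiler)
      res <- nciLP(tr)
      cx[[length(cx) + 1L]] <- data.frame(effect = eff, method = "LP",
                                          nci = res@nci,
                                          dimension = res@dimension)
      for (cause in others) {
        cr <- crLP(u, sp, cause, trace = tr)
        cs[[length(cs) + 1L]] <- data.frame(effect = eff, cause = cause,
                                            method = "LP", cr = cr@cr,
                                            nciFull = cr@nciFull,
                                            nciReduced = cr@nciReduced)
      }
      traces[[paste0(eff, ".LP")]] <- tr
    }
    if ("CE" %in% methods) {
      tr <- forwardSelectCE(u, sp, k = k, theiler = theiler)
      res <- nciCE(tr)
      cx[[length(cx) + 1L]] <- data.frame(effect = eff, method = "CE",
                                          nci = res@nci,
                                          dimension = res@dimension)
      for (cause in others) {
        cr <- crCE(u, sp, cause, trace = tr)
        cs[[length(cs) + 1L]] <- data.frame(effect = eff, cause = cause,
                                            method = "CE", cr = cr@cr,
                                            nciFull = cr@nciFull,
                                            nciReduced = cr@nciReduced)
      }
      traces[[paste0(eff, ".CE")]] <- tr
    }
  }
  list(complexity = do.call(rbind, cx), causality = do.call(rbind, cs),
       baroreflex = baro[c("brs", "bei", "nSequences", "nRamps")],
       traditional = traditional, window = prep$window, traces = traces)
}

#' Flatten a subject result into a named index vector
#'
#' Index names follow \code{nci_<effect>_<method>},
#' \code{cr_<cause>_to_<effect>_<method>}, \code{mu_}/\code{var_<series>},
#' \code{brs}, \code{bei}.
#'
#' @param res output of \code{\link{runSubject}}.
#' @return named numeric vector.
#' @export
subjectIndexes <- function(res) {
  out <- numeric(0)
  cx <- res$complexity
  if (!is.null(cx))
    out <- c(out, stats::setNames(cx$nci,
      sprintf("nci_%s_%s", cx$effect, cx$method)))
  cs <- res$causality
  if (!is.null(cs))
    out <- c(out, stats::setNames(cs$cr,
      sprintf("cr_%s_to_%s_%s", cs$cause, cs$effect, cs$method)))
  tr <- res$traditional
  if (!is.null(tr))
    out <- c(out, stats::setNames(c(tr$mean, tr$variance),
      c(sprintf("mu_%s", tr$series), sprintf("var_%s", tr$series))))
  if (!is.null(res$baroreflex))
    out <- c(out, brs = res$baroreflex$brs, bei = res$baroreflex$bei)
  out
}

#' Aggregate subject files into age-association tables
#'
#' Runs \code{\link{runSubject}} on every entry of a manifest (columns
#' \code{subject}, \code{file}, \code{age}, and optionally
#' \code{condition}), then associates every computed index with age within
#' each condition via the normality-gated correlation of
#' \code{\link{associateIndex}}. Unreadable or failing subjects are dropped
#' with a warning; fewer than 8 usable subjects in a condition is an error.
#'
#' @param manifest data.frame manifest.
#' @param methods,windowLength,seed,... forwarded to
#'   \code{\link{runSubject}}.
#' @return data.frame with one row per condition x index:
#'   \code{condition}, \code{index}, \code{n}, \code{method}, \code{r},
#'   \code{p}, \code{significant}; subjects used are kept in the
#'   \code{"nUsed"}/\code{"nFailed"} attributes.
#' @export
runCohort <- function(manifest, methods = c("MB", "LP", "CE"),
                      windowLength = 256, seed = NULL, ...) {
  if (is.null(manifest$condition)) manifest$condition <- "all"
  rows <- list(); failed <- 0L
  for (i in seq_len(nrow(manifest))) {
    res <- tryCatch(
      runSubject(manifest$file[i], methods = methods,
                 windowLength = windowLength,
                 seed = if (is.null(seed)) NULL else seed + i, ...),
      error = function(e) e)
    if (inherits(res, "error")) {
      warning(sprintf("subject %s skipped: %s", manifest$subject[i],
                      conditionMessage(res)))
      failed <- failed + 1L
      next
    }
    rows[[length(rows) + 1L]] <- c(list(subject = manifest$subject[i],
                                        age = manifest$age[i],
                                        condition = manifest$condition[i]),
                                   as.list(subjectIndexes(res)))
  }
  if (!length(rows))
    .cvcStop("no subject could be analyzed", "cvcInputError")
  tab <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  out <- list()
  for (cond in unique(tab$condition)) {
    sub <- tab[tab$condition == cond, , drop = FALSE]
    if (nrow(sub) < 8L)
      .cvcStop(sprintf("condition %s has %d usable subjects; need >= 8",
                       cond, nrow(sub)), "cvcInputError")
    for (idx in setdiff(names(sub), c("subject", "age", "condition"))) {
      a <- tryCatch(associateIndex(sub[[idx]], sub$age, index = idx),
                    error = function(e) NULL)
      if (is.null(a)) next
      a$condition <- cond
      out[[length(out) + 1L]] <- a[, c("condition", "index", "n", "method",
                                       "r", "p", "significant")]
    }
  }
  res <- do.call(rbind, out)
  attr(res, "nUsed") <- nrow(tab)
  attr(res, "nFailed") <- failed
  res
}

#' Serialize a subject result to JSON
#'
#' Writes the complexity/causality tables, baroreflex and traditional
#' indexes and the window record as a JSON object with fixed numeric
#' formatting, so identical runs give byte-identical files.
#'
#' @param res output of \code{\link{runSubject}}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeSubjectJSON <- function(res, path) {
  payload <- list(
    complexity = res$complexity,
    causality = res$causality,
    baroreflex = res$baroreflex,
    traditional = res$traditional,
    window = res$window[c("start", "score", "tries")])
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = 10,
                       na = "null")
  invisible(path)
}
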