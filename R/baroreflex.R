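# Sequence-method baroreflex analysis. All criteria operate on raw-unit
# series (thresholds are in ms and mmHg), on sliding overlapping 4-beat
# windows; inequalities are strict, exactly as conventionally printed.

.seqLen <- 4L

# correlation that tolerates a constant vector (returns 0)
.safeCor <- function(x, y) {
  if (sd(x) == 0 || sd(y) == 0) return(0)
  cor(x, y)
}

#' Find systolic-pressure ramps
#'
#' A SAP ramp is a 4-beat window with three consecutive same-sign SAP
#' changes, a total change larger than 1 mmHg in magnitude, and an absolute
#' correlation of SAP against the beat index larger than 0.85. Overlapping
#' windows are each counted.
#'
#' @param sap a \linkS4class{BeatSeries} (mmHg) or numeric vector of raw SAP
#'   values.
#' @return data.frame with one row per ramp: \code{start} (beat index),
#'   \code{direction} (+1/-1), \code{delta} (total SAP change, mmHg),
#'   \code{r} (correlation against beat index).
#' @export
findSapRamps <- function(sap) {
  v <- if (is(sap, "BeatSeries")) sap@values else as.numeric(sap)
  n <- length(v)
  out <- list()
  if (n >= .seqLen) {
    for (s in seq_len(n - .seqLen + 1L)) {
      w <- v[s:(s + .seqLen - 1L)]
      d <- diff(w)
      if (all(d > 0)) dir <- 1L
      else if (all(d < 0)) dir <- -1L
      else next
      delta <- w[.seqLen] - w[1]
      if (abs(delta) <= 1) next
      r <- .safeCor(seq_len(.seqLen), w)
      if (abs(r) <= 0.85) next
      out[[length(out) + 1L]] <- data.frame(start = s, direction = dir,
                                            delta = delta, r = r)
    }
  }
  if (!length(out))
    return(data.frame(start = integer(0), direction = integer(0),
                      delta = numeric(0), r = numeric(0)))
  do.call(rbind, out)
}

#' Find spontaneous baroreflex sequences
#'
#' A baroreflex sequence is a 4-beat window (three increases or decreases)
#' where HP and SAP change contemporaneously in the same direction (lag 0),
#' the total HP change exceeds 5 ms, the total SAP change exceeds 1 mmHg,
#' and the correlation in the [SAP, HP] plane exceeds 0.85. The slope of the
#' least-squares regression of HP on SAP within the window is the per-window
#' baroreflex gain.
#'
#' @param hp a \linkS4class{BeatSeries} (ms) or numeric vector of raw HP
#'   values.
#' @param sap a \linkS4class{BeatSeries} (mmHg) or numeric vector, same
#'   length as \code{hp}.
#' @return data.frame with one row per sequence: \code{start},
#'   \code{direction}, \code{slope} (ms/mmHg), \code{r}.
#' @export
findBaroreflexSequences <- function(hp, sap) {
  h <- if (is(hp, "BeatSeries")) hp@values else as.numeric(hp)
  s <- if (is(sap, "BeatSeries")) sap@values else as.numeric(sap)
  if (length(h) != length(s))
    .cvcStop("HP and SAP series must have the same length", "cvcInputError")
  n <- length(h)
  out <- list()
  if (n >= .seqLen) {
    for (st in seq_len(n - .seqLen + 1L)) {
      wh <- h[st:(st + .seqLen - 1L)]
      ws <- s[st:(st + .seqLen - 1L)]
      dh <- diff(wh)
      ds <- diff(ws)
      if (all(dh > 0) && all(ds > 0)) dir <- 1L
      else if (all(dh < 0) && all(ds < 0)) dir <- -1L
      else next
      if (abs(wh[.seqLen] - wh[1]) <= 5) next
      if (abs(ws[.seqLen] - ws[1]) <= 1) next
      r <- .safeCor(ws, wh)
      if (r <= 0.85) next
      slope <- sum((ws - mean(ws)) * (wh - mean(wh))) / sum((ws - mean(ws))^2)
      out[[length(out) + 1L]] <- data.frame(start = st, direction = dir,
                                            slope = slope, r = r)
    }
  }
  if (!length(out))
    return(data.frame(start = integer(0), direction = integer(0),
                      slope = numeric(0), r = numeric(0)))
  do.call(rbind, out)
}

#' Baroreflex sensitivity (sequence method)
#'
#' The unweighted mean of the per-sequence HP-on-SAP slopes, in ms/mmHg.
#' With no sequences the gain is undefined and \code{NA} is returned (never
#' zero, which would read as a real null gain).
#'
#' @param sequences output of \code{\link{findBaroreflexSequences}}.
#' @return mean slope (ms/mmHg), or \code{NA_real_}.
#' @export
brs <- function(sequences) {
  if (nrow(sequences) == 0L) return(NA_real_)
  mean(sequences$slope)
}

#' Baroreflex effectiveness index
#'
#' The number of baroreflex sequences divided by the number of qualifying
#' SAP ramps: the fraction of pressure ramps that evoke a measurable cardiac
#' baroreflex response, a causality-flavored index from SAP to HP. Undefined
#' (\code{NA}) when no ramp exists.
#'
#' @param sequences output of \code{\link{findBaroreflexSequences}}.
#' @param ramps output of \code{\link{findSapRamps}}.
#' @return BEI in [0, 1], or \code{NA_real_}.
#' @export
bei <- function(sequences, ramps) {
  if (nrow(ramps) == 0L) return(NA_real_)
  nrow(sequences) / nrow(ramps)
}

#' Full sequence-method analysis of one HP/SAP pair
#'
#' Convenience wrapper running \code{\link{findSapRamps}},
#' \code{\link{findBaroreflexSequences}}, \code{\link{brs}} and
#' \code{\link{bei}} on raw-unit series.
#'
#' @inheritParams findBaroreflexSequences
#' @return list with \code{brs}, \code{bei}, \code{nSequences},
#'   \code{nRamps}, \code{sequences}, \code{ramps}.
#' @export
baroreflexAnalysis <- function(hp, sap) {
  ramps <- findSapRamps(sap)
  seqs <- findBaroreflexSequences(hp, sap)
  list(brs = brs(seqs), bei = bei(seqs, ramps), nSequences = nrow(seqs),
       nRamps = nrow(ramps), sequences = seqs, ramps = ramps)
}
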