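#' Accessors for cvcausal objects
#'
#' Small accessor generics: \code{beatValues} returns the numeric vector(s)
#' of a series or universe, \code{seriesLabels}/\code{seriesUnit} the
#' identifiers, \code{nBeats}/\code{nSeries} the dimensions, \code{nci} and
#' \code{crValue} the scalar indexes, \code{optimalDimension} the selected
#' order/dimension and \code{selectedComponents} the lagged components of an
#' optimal embedding.
#'
#' @param x an object of the documented classes.
#' @return see the individual methods.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("beatValues", function(x) standardGeneric("beatValues"))
#' @rdname accessors
#' @export
setGeneric("seriesLabels", function(x) standardGeneric("seriesLabels"))
#' @rdname accessors
#' @export
setGeneric("seriesUnit", function(x) standardGeneric("seriesUnit"))
#' @rdname accessors
#' @export
setGeneric("nBeats", function(x) standardGeneric("nBeats"))
#' @rdname accessors
#' @export
setGeneric("nSeries", function(x) standardGeneric("nSeries"))
#' @rdname accessors
#' @export
setGeneric("nci", function(x) standardGeneric("nci"))
#' @rdname accessors
#' @export
setGeneric("crValue", function(x) standardGeneric("crValue"))
#' @rdname accessors
#' @export
setGeneric("optimalDimension", function(x) standardGeneric("optimalDimension"))
#' @rdname accessors
#' @export
setGeneric("selectedComponents", function(x) standardGeneric("selectedComponents"))

#' @rdname accessors
setMethod("beatValues", "BeatSeries", function(x) x@values)
#' @rdname accessors
setMethod("beatValues", "BeatUniverse", function(x) x@data)
#' @rdname accessors
setMethod("seriesLabels", "BeatSeries", function(x) x@label)
#' @rdname accessors
setMethod("seriesLabels", "BeatUniverse", function(x) colnames(x@data))
#' @rdname accessors
setMethod("seriesUnit", "BeatSeries", function(x) x@unit)
#' @rdname accessors
setMethod("seriesUnit", "BeatUniverse", function(x)
  stats::setNames(x@units, colnames(x@data)))
#' @rdname accessors
setMethod("nBeats", "BeatSeries", function(x) length(x@values))
#' @rdname accessors
setMethod("nBeats", "BeatUniverse", function(x) nrow(x@data))
#' @rdname accessors
setMethod("nSeries", "BeatUniverse", function(x) ncol(x@data))
#' @rdname accessors
setMethod("nci", "ComplexityResult", function(x) x@nci)
#' @rdname accessors
setMethod("crValue", "CausalityResult", function(x) x@cr)
#' @rdname accessors
setMethod("optimalDimension", "ComplexityResult", function(x) x@dimension)
#' @rdname accessors
setMethod("optimalDimension", "SelectionTrace", function(x) x@optimalDim)
#' @rdname accessors
setMethod("selectedComponents", "ComplexityResult", function(x) x@components)
#' @rdname accessors
setMethod("selectedComponents", "SelectionTrace", function(x)
  x@components[seq_len(x@optimalDim), , drop = FALSE])

setMethod("show", "BeatSeries", function(object) {
  v <- object@values
  cat(sprintf("BeatSeries %s [%s], %d beats, mean %.4g, var %.4g\n",
              object@label, object@unit, length(v), mean(v),
              mean((v - mean(v))^2)))
})

setMethod("show", "BeatUniverse", function(object) {
  cat(sprintf("BeatUniverse: %d series x %d beats%s\n", ncol(object@data),
              nrow(object@data),
              if (object@normalized) " (normalized)" else ""))
  cat("  series:", paste(sprintf("%s [%s]", colnames(object@data),
                                 object@units), collapse = ", "), "\n")
})

setMethod("show", "EmbeddingSpec", function(object) {
  cat(sprintf("EmbeddingSpec for effect %s, maximal lag p = %d\n",
              object@effect, as.integer(object@p)))
  cat("  minimum delays:",
      paste(sprintf("%s:%d", names(object@tau), as.integer(object@tau)),
            collapse = ", "), "\n")
})

setMethod("show", "EmbeddingMatrix", function(object) {
  cat(sprintf("EmbeddingMatrix for effect %s: %d rows (n = %d..%d), %d components\n",
              object@effect, nrow(object@Z), min(object@rows),
              max(object@rows), ncol(object@Z)))
})

setMethod("show", "MvarFit", function(object) {
  cat(sprintf("MvarFit: order %d, %d coefficients, lambda^2 = %.6g\n",
              as.integer(object@order), length(object@coefficients),
              object@lambda2))
})

setMethod("show", "ComplexityResult", function(object) {
  what <- if (object@method == "MB") "order" else "dimension"
  cat(sprintf("ComplexityResult [%s] effect %s: NCI = %.4f (optimal %s %d)\n",
              object@method, object@effect, object@nci, what,
              as.integer(object@dimension)))
})

setMethod("show", "CausalityResult", function(object) {
  cat(sprintf("CausalityResult [%s] %s -> %s: CR = %.4f (NCI %.4f vs %.4f %s)\n",
              object@method, object@cause, object@effect, object@cr,
              object@nciFull, object@nciReduced, object@form))
})

setMethod("show", "SelectionTrace", function(object) {
  cat(sprintf("SelectionTrace [%s] effect %s: %d additions, optimal dimension %d\n",
              object@method, object@effect, length(object@criterion),
              as.integer(object@optimalDim)))
  if (object@optimalDim > 0) {
    sel <- object@components[seq_len(object@optimalDim), ]
    cat("  optimal set:",
        paste(sprintf("%s(lag %d)", sel$source, sel$lag), collapse = ", "),
        "\n")
  }
})
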