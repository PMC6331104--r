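#' @name accessors
#' @title Accessors for toxrank data classes
#'
#' @description
#' `geneIds()` returns the gene universe of an object; `geneRanks()` the
#' named rank vector; `geneScores()` the named score vector; `modulated()`
#' the set of evidenced genes of a [RankedList-class]; `rankMethod()` the
#' label of an [AggregationResult-class]; `universeSize()` the number of
#' genes ranked.
#'
#' @param x a [RankedList-class], [AggregationResult-class] or
#'   [ExpressionPanel-class] object as applicable.
#' @return see Description.
NULL

#' @rdname accessors
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))
#' @rdname accessors
#' @export
setGeneric("geneRanks", function(x) standardGeneric("geneRanks"))
#' @rdname accessors
#' @export
setGeneric("geneScores", function(x) standardGeneric("geneScores"))
#' @rdname accessors
#' @export
setGeneric("modulated", function(x) standardGeneric("modulated"))
#' @rdname accessors
#' @export
setGeneric("rankMethod", function(x) standardGeneric("rankMethod"))
#' @rdname accessors
#' @export
setGeneric("universeSize", function(x) standardGeneric("universeSize"))

#' @rdname accessors
#' @export
setMethod("geneIds", "ExpressionPanel", function(x) rownames(x))
#' @rdname accessors
#' @export
setMethod("geneIds", "RankedList", function(x) names(x@ranks))
#' @rdname accessors
#' @export
setMethod("geneIds", "AggregationResult", function(x) names(x@rank))

#' @rdname accessors
#' @export
setMethod("geneRanks", "RankedList", function(x) x@ranks)
#' @rdname accessors
#' @export
setMethod("geneRanks", "AggregationResult", function(x) x@rank)

#' @rdname accessors
#' @export
setMethod("geneScores", "AggregationResult", function(x) x@score)

#' @rdname accessors
#' @export
setMethod("modulated", "RankedList", function(x) x@modulated)

#' @rdname accessors
#' @export
setMethod("rankMethod", "AggregationResult", function(x) x@method)

#' @rdname accessors
#' @export
setMethod("universeSize", "RankedList", function(x) length(x@ranks))
#' @rdname accessors
#' @export
setMethod("universeSize", "AggregationResult", function(x) length(x@rank))

#' Significance values of an aggregation result
#'
#' @param x an [AggregationResult-class]; only MEAN and RRA attach p-values.
#' @param adjusted return BH-adjusted values instead of raw ones.
#' @return named numeric vector, or `NULL` when the method assigns none.
#' @export
setGeneric("genePValues",
           function(x, adjusted = FALSE) standardGeneric("genePValues"))

#' @rdname genePValues
#' @export
setMethod("genePValues", "AggregationResult", function(x, adjusted = FALSE) {
  v <- if (adjusted) x@qvalue else x@pvalue
  if (length(v)) v else NULL
})

setMethod("show", "ExpressionPanel", function(object) {
  cd <- colData(object)
  cat("ExpressionPanel:", nrow(object), "genes x", ncol(object), "samples\n")
  cat("  compounds:", length(unique(cd$compound)),
      " systems:", paste(unique(cd$system), collapse = ","),
      " timepoints:", paste(sort(unique(cd$time)), collapse = ","), "h\n")
  cat("  dose levels:", paste(intersect(doseLevels, unique(cd$dose)),
                              collapse = ", "), "\n")
})

setMethod("show", "RankedList", function(object) {
  N <- length(object@ranks)
  cat("RankedList over", N, "genes;", length(object@modulated),
      "modulated,", N - length(object@modulated),
      "in the tied bottom block\n")
  top <- utils::head(sort(object@ranks), 5)
  cat("  top:", paste(names(top), round(top, 2), sep = "=",
                      collapse = ", "), "\n")
})

setMethod("show", "AggregationResult", function(object) {
  cat("AggregationResult [", object@method, "] over ",
      length(object@rank), " genes\n", sep = "")
  top <- utils::head(sort(object@rank), 5)
  cat("  top:", paste(names(top), round(top, 2), sep = "=",
                      collapse = ", "), "\n")
})
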