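#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames colData
#' @importFrom S4Vectors DataFrame
NULL

doseLevels <- c("control", "low", "middle", "high")

#' ExpressionPanel: gene x sample log2 expression with sample metadata
#'
#' A [SummarizedExperiment::SummarizedExperiment] subclass holding one
#' log2-scale expression matrix (assay `"log2"`) and per-sample metadata
#' columns `compound`, `dose` (one of control/low/middle/high), `time`
#' (hours), `replicate` and `system` (model-system label such as HH, RH,
#' RL, RK). Every compound slice must contain a vehicle-control dose group.
#'
#' @aliases ExpressionPanel-class
#' @exportClass ExpressionPanel
setClass("ExpressionPanel", contains = "SummarizedExperiment")

setValidity("ExpressionPanel", function(object) {
  msg <- character(0)
  if (!"log2" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'log2' is required")
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "gene ids (rownames) must be present and unique")
  cd <- colData(object)
  need <- c("compound", "dose", "time", "replicate", "system")
  miss <- setdiff(need, colnames(cd))
  if (length(miss))
    msg <- c(msg, paste0("missing sample metadata column(s): ",
                         paste(miss, collapse = ", ")))
  if (length(msg)) return(msg)
  if (!all(cd$dose %in% doseLevels))
    msg <- c(msg, "dose must be one of control/low/middle/high")
  if (any(cd$time < 0)) msg <- c(msg, "time must be non-negative")
  if (!all(is.finite(assay(object, "log2"))))
    msg <- c(msg, "expression values must be finite")
  hasCtrl <- tapply(cd$dose == "control", cd$compound, any)
  if (!all(hasCtrl))
    msg <- c(msg, paste0("compound(s) without a control group: ",
                         paste(names(hasCtrl)[!hasCtrl], collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Construct an ExpressionPanel
#'
#' @param values numeric gene x sample matrix of log2 expression with gene
#'   ids as rownames and sample ids as colnames.
#' @param sampleData data.frame of per-sample metadata with columns
#'   `sample_id`, `compound`, `dose`, `time`, `replicate`, `system`; rows
#'   are matched to matrix columns by `sample_id`, order irrelevant.
#' @return an [ExpressionPanel-class] object.
#' @export
ExpressionPanel <- function(values, sampleData) {
  if (is.null(colnames(values)))
    stop("'values' must have sample ids as colnames")
  if (!"sample_id" %in% colnames(sampleData))
    stop("'sampleData' must have a 'sample_id' column")
  if (anyDuplicated(sampleData$sample_id))
    stop("duplicate sample_id in metadata")
  extra <- setdiff(colnames(values), sampleData$sample_id)
  if (length(extra))
    stop("sample(s) in matrix absent from metadata: ",
         paste(extra, collapse = ", "))
  extra <- setdiff(sampleData$sample_id, colnames(values))
  if (length(extra))
    stop("sample(s) in metadata absent from matrix: ",
         paste(extra, collapse = ", "))
  sampleData <- sampleData[match(colnames(values), sampleData$sample_id), ,
                           drop = FALSE]
  cd <- DataFrame(sampleData[setdiff(colnames(sampleData), "sample_id")],
                  row.names = sampleData$sample_id)
  se <- SummarizedExperiment(assays = list(log2 = as.matrix(values)),
                             colData = cd)
  new("ExpressionPanel", se)
}

#' RankedList: extended partial ranking of a fixed gene universe
#'
#' Stores one ranking of all `N` universe genes where rank 1 is the
#' strongest evidence, tied genes carry midranks, and every gene outside
#' the `modulated` set shares a single tied bottom rank. With the default
#' midranked bottom block the rank sum is `N(N+1)/2`.
#'
#' @slot ranks named numeric vector of ranks (names are gene ids).
#' @slot modulated character vector of genes carrying evidence (not in the
#'   tied bottom block).
#' @aliases RankedList-class
#' @exportClass RankedList
setClass("RankedList",
         representation(ranks = "numeric", modulated = "character"))

setValidity("RankedList", function(object) {
  r <- object@ranks
  N <- length(r)
  msg <- character(0)
  if (N == 0L) return("empty ranking")
  if (is.null(names(r)) || anyDuplicated(names(r)))
    msg <- c(msg, "ranks must be uniquely named by gene id")
  if (any(r < 1 - 1e-9 | r > N + 1e-9))
    msg <- c(msg, "ranks must lie in [1, N]")
  if (length(msg)) return(msg)
  if (!all(object@modulated %in% names(r)))
    return("modulated genes must belong to the universe")
  k <- length(object@modulated)
  mod <- r[object@modulated]
  # modulated genes occupy (possibly midranked) positions 1..k
  if (k && abs(sum(mod) - k * (k + 1) / 2) > 1e-6 * max(k, 1))
    return("modulated ranks must be midranks of the top positions")
  bottom <- r[setdiff(names(r), object@modulated)]
  if (length(bottom) > 1L && diff(range(bottom)) > 1e-9)
    return("all non-modulated genes must share one tied rank")
  if (length(bottom) && bottom[1L] < (k + 1 + N) / 2 - 1e-9)
    return("the tied bottom rank must be at least the block midrank")
  TRUE
})

#' Construct a RankedList
#'
#' @param ranks named numeric vector of ranks over the full universe.
#' @param modulated character vector of modulated (evidenced) gene ids.
#' @return a [RankedList-class] object.
#' @export
RankedList <- function(ranks, modulated = character(0)) {
  new("RankedList", ranks = ranks, modulated = as.character(modulated))
}

#' AggregationResult: one aggregated ranking across compounds
#'
#' @slot method label of the aggregation method (e.g. "RRA", "MEAN").
#' @slot score named numeric vector of method scores.
#' @slot rank named numeric vector of midrank-tied final ranks.
#' @slot pvalue named numeric vector of per-gene significance values, or
#'   empty when the method assigns none.
#' @slot qvalue BH-adjusted `pvalue`, or empty.
#' @aliases AggregationResult-class
#' @exportClass AggregationResult
setClass("AggregationResult",
         representation(method = "character", score = "numeric",
                        rank = "numeric", pvalue = "numeric",
                        qvalue = "numeric"))

setValidity("AggregationResult", function(object) {
  N <- length(object@rank)
  msg <- character(0)
  if (length(object@method) != 1L) msg <- c(msg, "method must be length 1")
  if (N == 0L || is.null(names(object@rank)))
    msg <- c(msg, "ranks must be named by gene id")
  if (!identical(names(object@score), names(object@rank)))
    msg <- c(msg, "score and rank must share gene names")
  if (length(msg)) return(msg)
  if (abs(sum(object@rank) - N * (N + 1) / 2) > 1e-6 * N)
    msg <- c(msg, "rank sum must equal N(N+1)/2")
  for (sl in c("pvalue", "qvalue")) {
    v <- slot(object, sl)
    if (length(v) && !identical(names(v), names(object@rank)))
      msg <- c(msg, paste(sl, "must be empty or named like rank"))
  }
  if (length(msg)) msg else TRUE
})

AggregationResult <- function(method, score, rank, pvalue = numeric(0),
                              qvalue = numeric(0)) {
  new("AggregationResult", method = method, score = score, rank = rank,
      pvalue = pvalue, qvalue = qvalue)
}
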