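#' @rdname CountTable
#' @param x object to access.
#' @export
setGeneric("countMatrix", function(x) standardGeneric("countMatrix"))

#' @rdname CountTable
#' @export
setMethod("countMatrix", "CountTable", function(x) x@counts)

#' @rdname CountTable
#' @export
setGeneric("sampleIDs", function(x) standardGeneric("sampleIDs"))

#' @rdname CountTable
#' @export
setMethod("sampleIDs", "CountTable", function(x) rownames(x@counts))

#' @rdname CountTable
#' @export
setGeneric("taxonIDs", function(x) standardGeneric("taxonIDs"))

#' @rdname CountTable
#' @export
setMethod("taxonIDs", "CountTable", function(x) colnames(x@counts))

#' @rdname PairwiseMatrix
#' @param x a PairwiseMatrix.
#' @export
setGeneric("matrixKind", function(x) standardGeneric("matrixKind"))

#' @rdname PairwiseMatrix
#' @export
setMethod("matrixKind", "PairwiseMatrix", function(x) x@kind)

#' @rdname PairwiseMatrix
#' @export
setMethod("sampleIDs", "PairwiseMatrix", function(x) x@ids)

#' Extract the numeric matrix from a PairwiseMatrix
#'
#' @param x a [PairwiseMatrix-class].
#' @param ... ignored.
#' @return base numeric matrix with ID dimnames.
#' @export
setMethod("as.matrix", "PairwiseMatrix", function(x, ...) x@values)

#' Pair value lookup
#'
#' @param x a [PairwiseMatrix-class].
#' @param i,j sample IDs.
#' @return the stored value for the pair.
#' @export
setGeneric("pairValue", function(x, i, j) standardGeneric("pairValue"))

#' @rdname pairValue
#' @export
setMethod("pairValue", "PairwiseMatrix", function(x, i, j) {
  miss <- setdiff(c(i, j), x@ids)
  if (length(miss))
    stop("IDs absent from matrix: ", paste(miss, collapse = ", "))
  x@values[i, j]
})

#' @rdname NullModelResult
#' @param x a NullModelResult.
#' @export
setGeneric("nullScore", function(x) standardGeneric("nullScore"))

#' @rdname NullModelResult
#' @export
setMethod("nullScore", "NullModelResult", function(x) x@score)

#' @rdname NullModelResult
#' @export
setGeneric("isDegenerate", function(x) standardGeneric("isDegenerate"))

#' @rdname NullModelResult
#' @export
setMethod("isDegenerate", "NullModelResult", function(x) x@degenerate)

#' @rdname SyntheticDataset
#' @param x a SyntheticDataset.
#' @export
setGeneric("countTable", function(x) standardGeneric("countTable"))

#' @rdname SyntheticDataset
#' @export
setMethod("countTable", "SyntheticDataset", function(x) x@counts)

#' @rdname SyntheticDataset
#' @export
setGeneric("phyloTree", function(x) standardGeneric("phyloTree"))

#' @rdname SyntheticDataset
#' @export
setMethod("phyloTree", "SyntheticDataset", function(x) x@tree)

#' @rdname SyntheticDataset
#' @export
setGeneric("sampleData", function(x) standardGeneric("sampleData"))

#' @rdname SyntheticDataset
#' @export
setMethod("sampleData", "SyntheticDataset", function(x) x@metadata)

#' @rdname SyntheticDataset
#' @export
setGeneric("scenarioTruth", function(x) standardGeneric("scenarioTruth"))

#' @rdname SyntheticDataset
#' @export
setMethod("scenarioTruth", "SyntheticDataset", function(x) x@truth)

#' @rdname ProcessFractions
#' @param x a ProcessFractions.
#' @export
setGeneric("processCounts", function(x) standardGeneric("processCounts"))

#' @rdname ProcessFractions
#' @export
setMethod("processCounts", "ProcessFractions", function(x) x@counts)

#' @rdname ProcessFractions
#' @export
setGeneric("processPercentages", function(x)
  standardGeneric("processPercentages"))

#' @rdname ProcessFractions
#' @export
setMethod("processPercentages", "ProcessFractions", function(x)
  x@percentages)

#' @rdname SampleGrouping
#' @param x a SampleGrouping.
#' @export
setGeneric("groupingPairs", function(x) standardGeneric("groupingPairs"))

#' @rdname SampleGrouping
#' @export
setMethod("groupingPairs", "SampleGrouping", function(x) x@pairs)

setMethod("show", "CountTable", function(object) {
  m <- object@counts
  cat("CountTable:", nrow(m), "samples x", ncol(m), "taxa;",
      format(sum(m), big.mark = ","), "total counts\n")
})

setMethod("show", "PairwiseMatrix", function(object) {
  cat("PairwiseMatrix <", object@kind, ">: ",
      length(object@ids), " x ", length(object@ids), " IDs\n", sep = "")
})

setMethod("show", "NullModelResult", function(object) {
  cat("NullModelResult: observed =", signif(object@observed, 4),
      "| null", signif(object@nullMean, 4), "+/-",
      signif(object@nullSD, 4),
      "| score =", signif(object@score, 4),
      if (object@degenerate) "(degenerate)" else "", "\n")
})

setMethod("show", "ProcessFractions", function(object) {
  cat("ProcessFractions [", object@grouping, "]: ", object@nPairs,
      " pairs (", object@nExcluded, " excluded)\n", sep = "")
  print(round(object@percentages, 1))
})

setMethod("show", "SyntheticDataset", function(object) {
  cat("SyntheticDataset [", object@truth@scenario, "]: ",
      nrow(object@counts@counts), " samples, ",
      ncol(object@counts@counts), " taxa\n", sep = "")
})

#' Tabulate process fractions
#'
#' @param x a [ProcessFractions-class] object.
#' @param row.names,optional,... passed through for S3 compatibility.
#' @return one-row data.frame: grouping, the five process percentages,
#'   n_pairs and n_excluded.
#' @export
as.data.frame.ProcessFractions <- function(x, row.names = NULL,
                                           optional = FALSE, ...) {
  out <- data.frame(grouping = x@grouping, t(x@percentages),
                    n_pairs = x@nPairs, n_excluded = x@nExcluded,
                    check.names = FALSE)
  rownames(out) <- row.names
  out
}
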