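#' @importFrom BiocGenerics counts
NULL

#' Accessors for tagnorm classes
#'
#' \code{counts} returns the count matrix, \code{groups} the two-level sample
#' assignment, \code{libSizes} the per-sample library sizes.
#'
#' @param object,x a \linkS4class{TagCountSet} or result object.
#' @param ... unused.
#' @return the corresponding slot content.
#' @name accessors
#' @aliases counts,TagCountSet-method
#' @examples
#' tcs <- TagCountSet(matrix(1:6, 3, 2), groups = c("A", "B"))
#' counts(tcs); groups(tcs); libSizes(tcs)
NULL

#' @rdname accessors
#' @export
setMethod("counts", "TagCountSet", function(object, ...) {
  SummarizedExperiment::assay(object, "counts")
})

#' @rdname accessors
#' @export
setGeneric("groups", function(x, ...) standardGeneric("groups"))

#' @rdname accessors
#' @export
setMethod("groups", "TagCountSet", function(x, ...) {
  SummarizedExperiment::colData(x)$group
})

#' @rdname accessors
#' @export
setGeneric("libSizes", function(x, ...) standardGeneric("libSizes"))

#' @rdname accessors
#' @export
setMethod("libSizes", "TagCountSet", function(x, ...) {
  setNames(SummarizedExperiment::colData(x)$libSize, colnames(x))
})

#' @rdname accessors
#' @export
setGeneric("normFactors", function(x, ...) standardGeneric("normFactors"))

#' @rdname accessors
#' @export
setMethod("normFactors", "NormalizationResult", function(x, ...) x@factors)

#' @rdname accessors
#' @export
setGeneric("effectiveLibSizes",
           function(x, ...) standardGeneric("effectiveLibSizes"))

#' @rdname accessors
#' @export
setMethod("effectiveLibSizes", "NormalizationResult",
          function(x, ...) x@effectiveSizes)

#' @rdname accessors
#' @export
setGeneric("normMethod", function(x, ...) standardGeneric("normMethod"))

#' @rdname accessors
#' @export
setMethod("normMethod", "NormalizationResult", function(x, ...) x@method)

#' @rdname accessors
#' @export
setGeneric("scores", function(x, ...) standardGeneric("scores"))

#' @rdname accessors
#' @export
setMethod("scores", "RankedList", function(x, ...) x@scores)

#' @rdname accessors
#' @export
setGeneric("rankOrder", function(x, ...) standardGeneric("rankOrder"))

#' @rdname accessors
#' @export
setMethod("rankOrder", "RankedList", function(x, ...) x@ord)

#' @rdname accessors
#' @export
setGeneric("direction", function(x, ...) standardGeneric("direction"))

#' @rdname accessors
#' @export
setMethod("direction", "RankedList", function(x, ...) x@direction)

#' @rdname accessors
#' @export
setMethod("direction", "DEGSetEstimate", function(x, ...) x@direction)

#' @rdname accessors
#' @export
setGeneric("posteriorDE", function(x, ...) standardGeneric("posteriorDE"))

#' @rdname accessors
#' @export
setMethod("posteriorDE", "DEGSetEstimate", function(x, ...) x@posteriorDE)

#' @rdname accessors
#' @export
setGeneric("pdegHat", function(x, ...) standardGeneric("pdegHat"))

#' @rdname accessors
#' @export
setMethod("pdegHat", "DEGSetEstimate", function(x, ...) x@pdegHat)

#' @rdname accessors
#' @export
setGeneric("paHat", function(x, ...) standardGeneric("paHat"))

#' @rdname accessors
#' @export
setMethod("paHat", "DEGSetEstimate", function(x, ...) x@paHat)

#' @rdname accessors
#' @export
setGeneric("degFlags", function(x, ...) standardGeneric("degFlags"))

#' @rdname accessors
#' @export
setMethod("degFlags", "DEGSetEstimate", function(x, ...) x@degFlags)

#' @rdname accessors
#' @export
setGeneric("tbtFactors", function(x, ...) standardGeneric("tbtFactors"))

#' @rdname accessors
#' @export
setMethod("tbtFactors", "TbTResult", function(x, ...) x@tbt@factors)

#' Simulation truth stored alongside simulated counts
#'
#' @param x a \linkS4class{TagCountSet} produced by \code{\link{simulateCounts}}.
#' @return a \code{DataFrame} with per-gene columns \code{isDE},
#'   \code{direction} (+1 A-higher, -1 B-higher, 0 for non-DE) and
#'   \code{foldChange}.
#' @export
simTruth <- function(x) {
  rd <- SummarizedExperiment::rowData(x)
  if (!all(c("isDE", "direction", "foldChange") %in% colnames(rd)))
    stop("object carries no simulation truth")
  rd[, c("isDE", "direction", "foldChange")]
}

setMethod("show", "NormalizationResult", function(object) {
  cat(sprintf("NormalizationResult (%s), %d samples\n", object@method,
              length(object@factors)))
  cat("factors: ", paste(sprintf("%.4f", object@factors), collapse = " "), "\n")
  if (!is.na(object@refSample))
    cat("reference sample:", object@refSample, "\n")
})

setMethod("show", "DEGSetEstimate", function(object) {
  cat(sprintf(
    "DEGSetEstimate: %d genes, pdegHat = %.4f, paHat = %.4f, %d flagged\n",
    length(object@posteriorDE), object@pdegHat, object@paHat,
    sum(object@degFlags)))
  if (!object@converged) cat("warning: fixed point did not converge\n")
})

setMethod("show", "RankedList", function(object) {
  cat(sprintf("RankedList (%s): %d genes, scores ranked %s\n", object@method,
              length(object@scores),
              if (object@higherIsBetter) "descending" else "ascending"))
})

setMethod("show", "TbTResult", function(object) {
  cat(sprintf("TbTResult (iteration %d): %d genes eliminated (pdegHat = %.4f)\n",
              object@iteration, length(object@eliminated),
              object@step2@pdegHat))
  cat("TbT factors: ",
      paste(sprintf("%.4f", object@tbt@factors), collapse = " "), "\n")
})
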