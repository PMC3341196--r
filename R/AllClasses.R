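#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom stats median optimize quantile rlnorm rgamma rnbinom rpois
#'   runif setNames splinefun var wilcox.test dbinom ks.test cor
#' @importFrom utils read.delim write.table
NULL

#' TagCountSet: a tag count matrix with a two-group design
#'
#' A thin extension of \linkS4class{SummarizedExperiment} holding a genes x
#' samples matrix of non-negative tag counts (assay \code{"counts"}), a
#' two-level group assignment and per-sample library sizes in \code{colData}.
#' The first group level plays the role of "Sample A" in all M-A statistics
#' (log ratios are oriented B over A) and in the directional bookkeeping
#' downstream.
#'
#' @slot . inherits all slots from SummarizedExperiment.
#' @export
setClass("TagCountSet", contains = "SummarizedExperiment")

setValidity("TagCountSet", function(object) {
  msg <- NULL
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    return("assay 'counts' is required")
  cnt <- SummarizedExperiment::assay(object, "counts")
  if (nrow(cnt) < 1L) msg <- c(msg, "at least one gene is required")
  if (ncol(cnt) < 2L) msg <- c(msg, "at least two samples are required")
  if (any(cnt < 0)) msg <- c(msg, "counts must be non-negative")
  cd <- SummarizedExperiment::colData(object)
  if (!all(c("group", "libSize") %in% colnames(cd)))
    return("colData must contain 'group' and 'libSize'")
  grp <- cd$group
  if (nlevels(grp) != 2L || any(table(grp) < 1L))
    msg <- c(msg, "exactly two group labels, each occurring at least once")
  ls <- cd$libSize
  if (length(ls) != ncol(cnt) || any(!is.finite(ls)) || any(ls <= 0))
    msg <- c(msg, "library sizes must be strictly positive, one per sample")
  if (anyDuplicated(rownames(cnt)))
    msg <- c(msg, "gene identifiers must be unique")
  if (is.null(msg)) TRUE else msg
})

#' Construct a TagCountSet
#'
#' @param counts numeric matrix of non-negative counts, genes in rows. Raw
#'   input is integer; RPM-scaled derivatives are fractional.
#' @param groups per-sample labels; exactly two distinct values. The first
#'   level (sorted order for character input) is treated as Sample A.
#' @param libSizes per-sample library sizes; defaults to column sums.
#' @return A \linkS4class{TagCountSet}.
#' @examples
#' tcs <- TagCountSet(matrix(1:6, 3, 2), groups = c("A", "B"))
#' libSizes(tcs)
#' @export
TagCountSet <- function(counts, groups, libSizes = colSums(counts)) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("gene_%05d", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("sample_%02d", seq_len(ncol(counts)))
  if (length(groups) != ncol(counts))
    stop("length of 'groups' (", length(groups),
         ") must equal the number of samples (", ncol(counts), ")")
  if (!is.factor(groups)) groups <- factor(groups, levels = sort(unique(groups)))
  cd <- S4Vectors::DataFrame(group = groups, libSize = as.numeric(libSizes),
                             row.names = colnames(counts))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts), colData = cd)
  new("TagCountSet", se)
}

#' Per-sample scaling factors with effective library sizes
#'
#' @slot factors per-sample positive scaling factors, geometric mean 1.
#' @slot libSizes per-sample library sizes the factors refer to.
#' @slot effectiveSizes \code{libSizes * factors}.
#' @slot method provenance tag: "rpm", "tmm", "tbt" or "tbtN" (iterated).
#' @slot refSample index of the reference sample used for pairwise M/A
#'   (NA for methods without a reference).
#' @export
setClass("NormalizationResult",
  representation(factors = "numeric", libSizes = "numeric",
                 effectiveSizes = "numeric", method = "character",
                 refSample = "integer"))

setValidity("NormalizationResult", function(object) {
  msg <- NULL
  f <- object@factors
  if (any(!is.finite(f)) || any(f <= 0)) msg <- c(msg, "factors must be positive")
  if (length(f) && abs(log(geomean(f))) > 1e-8)
    msg <- c(msg, "factors must have geometric mean 1")
  if (length(object@libSizes) != length(f) ||
      length(object@effectiveSizes) != length(f))
    msg <- c(msg, "factors, libSizes and effectiveSizes must have equal length")
  else if (any(abs(object@effectiveSizes - object@libSizes * f) >
               1e-8 * object@libSizes))
    msg <- c(msg, "effectiveSizes must equal libSizes * factors")
  if (is.null(msg)) TRUE else msg
})

NormalizationResult <- function(factors, libSizes, method,
                                refSample = NA_integer_) {
  factors <- factors / geomean(factors)
  new("NormalizationResult", factors = factors, libSizes = libSizes,
      effectiveSizes = libSizes * factors, method = method,
      refSample = as.integer(refSample))
}

#' Common and tagwise negative-binomial dispersion estimates
#'
#' @slot common scalar dispersion phi maximizing the summed conditional
#'   likelihood across genes.
#' @slot tagwise per-gene dispersions shrunk toward the common value
#'   (length 0 when only the common estimate was computed).
#' @slot priorWeight shrinkage strength (equivalent observations) used for
#'   the tagwise fit.
#' @export
setClass("DispersionEstimate",
  representation(common = "numeric", tagwise = "numeric",
                 priorWeight = "numeric"))

setValidity("DispersionEstimate", function(object) {
  if (object@common < 0) return("common dispersion must be >= 0")
  if (length(object@tagwise) && any(object@tagwise < 0))
    return("tagwise dispersions must be >= 0")
  TRUE
})

#' A ranked gene list from a two-group test
#'
#' @slot scores per-gene ranking statistic (p-values for the exact test,
#'   posterior DE probabilities for the empirical Bayes detector).
#' @slot ord permutation of gene indices from most to least differentially
#'   expressed; ties broken by gene index.
#' @slot direction per-gene sign: +1 higher in group A, -1 higher in group B.
#' @slot higherIsBetter TRUE when large scores mean stronger evidence.
#' @slot method provenance tag.
#' @export
setClass("RankedList",
  representation(scores = "numeric", ord = "integer", direction = "integer",
                 higherIsBetter = "logical", method = "character"))

setValidity("RankedList", function(object) {
  s <- object@scores
  if (length(object@ord) != length(s)) return("ord must index every gene")
  key <- if (object@higherIsBetter) -s else s
  expect <- order(key, seq_along(s))
  if (!identical(object@ord, as.integer(expect)))
    return("ord must sort scores with ties broken by gene index")
  TRUE
})

RankedList <- function(scores, direction, higherIsBetter, method) {
  key <- if (higherIsBetter) -scores else scores
  new("RankedList", scores = scores,
      ord = as.integer(order(key, seq_along(scores))),
      direction = as.integer(direction),
      higherIsBetter = higherIsBetter, method = method)
}

#' Bootstrap particles for the empirical NB prior
#'
#' Per-particle (mu, phi) fits on effective-library-scaled counts: pooled fits
#' for the no-DE model and per-group fits (A, B) for the DE model. mu is the
#' expression rate per unit effective library size.
#'
#' @export
setClass("PriorParticles",
  representation(mu = "numeric", phi = "numeric",
                 muA = "numeric", phiA = "numeric",
                 muB = "numeric", phiB = "numeric",
                 nBootstrap = "integer", seed = "integer"))

setValidity("PriorParticles", function(object) {
  n <- object@nBootstrap
  lens <- c(length(object@mu), length(object@phi), length(object@muA),
            length(object@phiA), length(object@muB), length(object@phiB))
  if (any(lens != n)) return("particle vectors must have length nBootstrap")
  if (any(object@mu <= 0) || any(object@muA <= 0) || any(object@muB <= 0))
    return("all particle means must be > 0")
  if (any(object@phi < 0) || any(object@phiA < 0) || any(object@phiB < 0))
    return("all particle dispersions must be >= 0")
  TRUE
})

#' Estimated set of potential DEGs
#'
#' @slot posteriorDE per-gene posterior probability of differential expression.
#' @slot pdegHat estimated proportion of DEGs (converged mixture weight).
#' @slot paHat among flagged genes, fraction higher in group A (0.5 by
#'   convention when nothing is flagged).
#' @slot degFlags per-gene potential-DEG flag.
#' @slot direction per-gene +1 (A-higher) / -1 (B-higher).
#' @slot converged whether the fixed-point iteration converged.
#' @slot nIter iterations used.
#' @export
setClass("DEGSetEstimate",
  representation(posteriorDE = "numeric", pdegHat = "numeric",
                 paHat = "numeric", degFlags = "logical",
                 direction = "integer", converged = "logical",
                 nIter = "integer"))

setValidity("DEGSetEstimate", function(object) {
  msg <- NULL
  p <- object@posteriorDE
  if (any(p < 0 | p > 1)) msg <- c(msg, "posteriorDE must lie in [0, 1]")
  if (object@pdegHat < 0 || object@pdegHat > 1)
    msg <- c(msg, "pdegHat must lie in [0, 1]")
  if (object@paHat < 0 || object@paHat > 1)
    msg <- c(msg, "paHat must lie in [0, 1]")
  if (length(object@degFlags) &&
      sum(object@degFlags) != round(object@pdegHat * length(p)))
    msg <- c(msg, "number of flags must equal round(pdegHat * G)")
  if (is.null(msg)) TRUE else msg
})

#' Result of the three-step DEG-elimination (TbT) normalization
#'
#' @slot step1 temporary TMM normalization on the full matrix.
#' @slot step2 empirical-Bayes potential-DEG estimate.
#' @slot step3 TMM normalization on the DEG-free submatrix.
#' @slot tbt final factors: step-3 factors times the ratio of library sizes
#'   after/before elimination, rescaled to geometric mean 1.
#' @slot eliminated identifiers of the eliminated genes.
#' @slot iteration refinement round that produced this result (0 = original).
#' @export
setClass("TbTResult",
  representation(step1 = "NormalizationResult", step2 = "DEGSetEstimate",
                 step3 = "NormalizationResult", tbt = "NormalizationResult",
                 eliminated = "character", iteration = "integer"))
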