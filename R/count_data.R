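#' Read a tag count matrix from a TSV file
#'
#' Expects a header row of sample names and one gene per row with the gene
#' identifier in the first column, the dialect written by
#' \code{\link{writeCounts}}.
#'
#' @param path path to a tab-separated count file.
#' @param groups per-sample group labels (length = number of count columns).
#' @return a \linkS4class{TagCountSet} with library sizes set to column sums
#'   and gene order preserved.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeCounts(TagCountSet(matrix(1:4, 2), c("A", "B")), tf)
#' readCounts(tf, groups = c("A", "B"))
#' @export
readCounts <- function(path, groups) {
  if (!file.exists(path)) stop("count file not found: ", path)
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (ncol(df) < 3L) stop("need a gene-id column plus at least two samples")
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) {
    dup <- ids[duplicated(ids)][1L]
    stop("duplicate gene identifier: ", dup)
  }
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric cells in ", path)
  neg <- which(rowSums(m < 0) > 0)
  if (length(neg))
    stop("negative count in row ", neg[1L], " (gene ", ids[neg[1L]], ")")
  rownames(m) <- ids
  TagCountSet(m, groups = groups)
}

#' Write a tag count matrix as TSV
#'
#' @param x a \linkS4class{TagCountSet} (or plain matrix with dimnames).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeCounts <- function(x, path) {
  m <- if (is(x, "TagCountSet")) counts(x) else as.matrix(x)
  df <- data.frame(gene = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Scale each sample to reads per million
#'
#' Rescales every column so that it totals one million, preserving within-
#' column count ratios and group labels. Idempotent.
#'
#' @param x a \linkS4class{TagCountSet}.
#' @return a fractional \linkS4class{TagCountSet} whose library sizes are all
#'   1e6.
#' @export
rpmScale <- function(x) {
  ls <- libSizes(x)
  zero <- which(ls <= 0)
  if (length(zero))
    stop("zero library size for sample ", names(ls)[zero[1L]])
  m <- sweep(counts(x), 2L, ls / 1e6, "/")
  TagCountSet(m, groups = groups(x), libSizes = rep(1e6, ncol(m)))
}

#' Identity normalization on the RPM scale
#'
#' All factors 1: normalized expression is then count / library size, i.e.
#' plain depth (RPM) scaling. Useful as the baseline in M-A statistics.
#'
#' @param x a \linkS4class{TagCountSet}.
#' @return a \linkS4class{NormalizationResult} with method \code{"rpm"}.
#' @export
rpmNormalization <- function(x) {
  NormalizationResult(rep(1, ncol(x)), libSizes(x), method = "rpm")
}

#' Per-gene M-A statistics between the two groups
#'
#' M is the log2 ratio of the group-B mean to the group-A mean of normalized
#' expression y / (N * f); A is the average of the two log2 group means.
#' Genes with a zero mean in either group have no defined log ratio: they are
#' flagged \code{defined = FALSE} and carry NA, never +/-Inf, and are excluded
#' from any median or trimmed statistic downstream.
#'
#' @param x a \linkS4class{TagCountSet}.
#' @param norm a \linkS4class{NormalizationResult} covering the samples of
#'   \code{x}.
#' @return a \code{DataFrame} with columns \code{m}, \code{a}, \code{defined}.
#' @export
maStats <- function(x, norm) {
  if (length(norm@factors) != ncol(x))
    stop("normalization result does not cover all samples")
  eff <- libSizes(x) * norm@factors
  y <- sweep(counts(x), 2L, eff, "/")
  grp <- groups(x)
  isA <- grp == levels(grp)[1L]
  meanA <- rowMeans(y[, isA, drop = FALSE])
  meanB <- rowMeans(y[, !isA, drop = FALSE])
  ok <- meanA > 0 & meanB > 0
  m <- a <- rep(NA_real_, nrow(x))
  m[ok] <- log2(meanB[ok]) - log2(meanA[ok])
  a[ok] <- (log2(meanB[ok]) + log2(meanA[ok])) / 2
  S4Vectors::DataFrame(m = m, a = a, defined = ok, row.names = rownames(x))
}
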