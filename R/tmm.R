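#' Choose the reference sample for pairwise TMM
#'
#' The reference is the sample whose upper quartile of depth-scaled counts is
#' closest to the mean upper quartile across samples; ties go to the lowest
#' index.
#'
#' @param x a \linkS4class{TagCountSet}.
#' @return an integer sample index.
#' @export
selectReference <- function(x) {
  cnt <- counts(x)
  if (all(cnt == 0)) stop("all-zero count matrix: no reference can be chosen")
  f75 <- unname(apply(cnt, 2L, quantile, probs = 0.75)) / unname(libSizes(x))
  unname(which.min(abs(f75 - mean(f75)))[1L])
}

#' Pairwise trimmed-mean-of-M-values log2 factor
#'
#' Computes the weighted, doubly trimmed mean of per-gene log2 ratios of one
#' library against a reference. Only genes with positive counts in both
#' libraries contribute (undefined log ratios are never imputed). Per gene,
#' M = log2((yo/No)/(yr/Nr)), A = log2((yo/No)(yr/Nr))/2, and the precision
#' weight is the inverse delta-method (binomial) variance of M,
#' 1/((No-yo)/(No yo) + (Nr-yr)/(Nr yr)). Genes in the most extreme
#' \code{trimM} tails of M (each side) or \code{trimA} tails of A (each side)
#' are removed before the weighted mean is taken.
#'
#' @param obs,ref per-gene counts of the observed and reference library.
#' @param libObs,libRef library sizes.
#' @param trimM,trimA trim fractions per side, in [0, 0.5).
#' @param doWeighting use precision weights (TRUE) or unit weights.
#' @return the log2 scaling factor of \code{obs} relative to \code{ref}.
#' @export
tmmPairFactor <- function(obs, ref, libObs, libRef,
                          trimM = 0.30, trimA = 0.05, doWeighting = TRUE) {
  stopifnot(libObs > 0, libRef > 0,
            trimM >= 0, trimM < 0.5, trimA >= 0, trimA < 0.5)
  pos <- obs > 0 & ref > 0
  obs <- obs[pos]; ref <- ref[pos]
  n <- length(obs)
  if (n == 0L)
    stop("no genes with positive counts in both libraries")
  m <- log2(obs / libObs) - log2(ref / libRef)
  a <- (log2(obs / libObs) + log2(ref / libRef)) / 2
  w <- if (doWeighting)
    1 / ((libObs - obs) / (libObs * obs) + (libRef - ref) / (libRef * ref))
  else rep(1, n)
  loM <- floor(n * trimM) + 1
  hiM <- n + 1 - loM
  loA <- floor(n * trimA) + 1
  hiA <- n + 1 - loA
  rM <- rank(m); rA <- rank(a)
  keep <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
  if (!any(keep))
    stop("no genes survive the trims; use smaller trimM/trimA")
  f <- sum(w[keep] * m[keep]) / sum(w[keep])
  if (abs(f) < 1e-6) f <- 0
  f
}

#' TMM scaling factors for all samples
#'
#' Each sample's factor comes from \code{\link{tmmPairFactor}} against the
#' reference chosen by \code{\link{selectReference}} (the reference itself has
#' log2 factor 0); factors are then rescaled so their geometric mean is 1,
#' which makes factors from different methods directly comparable.
#'
#' The default trims (30\% per side on M, 5\% per side on A) encode the
#' built-in assumption that up to 60\% of genes may be differentially
#' expressed, with no directional bias.
#'
#' @param x a \linkS4class{TagCountSet}.
#' @param trimM,trimA trim fractions per side.
#' @param doWeighting use precision weights.
#' @return a \linkS4class{NormalizationResult} with method \code{"tmm"}.
#' @examples
#' tcs <- TagCountSet(matrix(rpois(600, 50), 100, 6),
#'                    groups = rep(c("A", "B"), each = 3))
#' normFactors(tmmFactors(tcs))
#' @export
tmmFactors <- function(x, trimM = 0.30, trimA = 0.05, doWeighting = TRUE) {
  cnt <- counts(x)
  ls <- libSizes(x)
  refIdx <- selectReference(x)
  logf <- vapply(seq_len(ncol(cnt)), function(j) {
    if (j == refIdx) return(0)
    tmmPairFactor(cnt[, j], cnt[, refIdx], ls[j], ls[refIdx],
                  trimM = trimM, trimA = trimA, doWeighting = doWeighting)
  }, numeric(1))
  f <- 2^logf
  NormalizationResult(setNames(f / geomean(f), colnames(cnt)), ls,
                      method = "tmm", refSample = refIdx)
}
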