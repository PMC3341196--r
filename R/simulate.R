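#' Synthetic mean-dispersion table
#'
#' Generates (mu, phi) pairs emulating the empirical behaviour of biological
#' replicate tag counts: variance V = mu + phi * mu^2 with the dispersion phi
#' large at small means and small at large means. Means are log-normal
#' (meanlog 2.0, sdlog 1.5); phi = 0.1 + 2.5/mu, jittered by a log-normal
#' factor (sdlog 0.3), giving a clear negative mu-phi rank correlation.
#'
#' @param n number of pairs.
#' @param seed integer seed (mandatory; the draw is deterministic under it).
#' @return a \code{data.frame} with columns \code{mu}, \code{phi} and
#'   attribute \code{source = "synthetic"}.
#' @export
syntheticMeanDispersionTable <- function(n, seed) {
  stopifnot(n >= 1)
  withSeed(seed, {
    mu <- rlnorm(n, meanlog = 2.0, sdlog = 1.5)
    phi <- (0.1 + 2.5 / mu) * rlnorm(n, meanlog = 0, sdlog = 0.3)
    out <- data.frame(mu = mu, phi = phi)
    attr(out, "source") <- "synthetic"
    out
  })
}

#' Read a two-column mean-dispersion table
#'
#' @param path TSV with columns mu and phi (header optional; first two numeric
#'   columns are used).
#' @return a \code{data.frame} with columns \code{mu}, \code{phi}.
#' @export
readMeanDispersionTable <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t")
  if (!is.numeric(df[[1L]]))
    df <- read.delim(path, header = FALSE, sep = "\t")
  out <- data.frame(mu = as.numeric(df[[1L]]), phi = as.numeric(df[[2L]]))
  if (nrow(out) == 0L || any(out$mu <= 0) || any(out$phi < 0))
    stop("mean-dispersion table must have mu > 0 and phi >= 0")
  attr(out, "source") <- "file"
  out
}

#' Fold-change models for simulated DEGs
#'
#' \code{fixedFoldChange(c)} gives every DEG the same fold change;
#' \code{gammaFoldChange(shape, scale, offset)} draws offset + gamma
#' variates. The defaults (shape 2.0, scale 0.5, offset 1.2) give minimum and
#' mean fold changes of about 1.2 and 2.2.
#'
#' @param fc,shape,scale,offset model parameters.
#' @return a fold-change model object for \code{\link{sampleFoldChanges}}.
#' @export
fixedFoldChange <- function(fc = 4) {
  stopifnot(fc >= 1)
  structure(list(type = "fixed", fc = fc), class = "foldChangeModel")
}

#' @rdname fixedFoldChange
#' @export
gammaFoldChange <- function(shape = 2.0, scale = 0.5, offset = 1.2) {
  if (offset < 1) stop("offset must be >= 1: fold changes must exceed 1")
  structure(list(type = "gamma", shape = shape, scale = scale,
                 offset = offset), class = "foldChangeModel")
}

#' Draw per-gene fold changes from a model
#'
#' @param model a fold-change model from \code{\link{fixedFoldChange}} or
#'   \code{\link{gammaFoldChange}}.
#' @param nDE number of DE genes.
#' @param seed integer seed.
#' @return numeric vector of length \code{nDE}, all values >= 1.
#' @export
sampleFoldChanges <- function(model, nDE, seed) {
  stopifnot(inherits(model, "foldChangeModel"), nDE >= 0)
  if (model$type == "fixed") return(rep(model$fc, nDE))
  withSeed(seed, model$offset +
             rgamma(nDE, shape = model$shape, scale = model$scale))
}

#' Simulate a two-group NB tag count matrix with known DE truth
#'
#' Per gene, a (mu, phi) pair is resampled jointly from the mean-dispersion
#' table (preserving their coupling); round(nGenes * pdeg) genes are made
#' differentially expressed, round(.. * pa) of them higher in group A, at
#' positions shuffled under the seed. A DE gene's up-regulated group gets mean
#' mu * foldChange, the other group mean mu; every count is then an
#' independent NB draw with variance mu + phi * mu^2 (Poisson when phi = 0).
#'
#' Rounding is R's round-half-to-even throughout.
#'
#' @param nGenes number of genes (default 20000).
#' @param nA,nB replicates per group (default 3 and 3).
#' @param pdeg proportion of DE genes in [0, 1].
#' @param pa among DE genes, proportion higher in group A.
#' @param foldChange a fold-change model (default \code{fixedFoldChange(4)}).
#' @param table a mean-dispersion table; default is
#'   \code{syntheticMeanDispersionTable(nGenes, seed)}.
#' @param seed integer seed.
#' @return a \linkS4class{TagCountSet} whose \code{rowData} carries the truth
#'   (see \code{\link{simTruth}}) and whose \code{metadata} echoes the
#'   parameters.
#' @examples
#' sim <- simulateCounts(nGenes = 200, pdeg = 0.2, pa = 0.9, seed = 1)
#' table(simTruth(sim)$isDE)
#' @export
simulateCounts <- function(nGenes = 20000L, nA = 3L, nB = 3L, pdeg = 0.20,
                           pa = 0.90, foldChange = fixedFoldChange(4),
                           table = NULL, seed) {
  stopifnot(nGenes >= 1, nA >= 1, nB >= 1,
            pdeg >= 0, pdeg <= 1, pa >= 0, pa <= 1)
  if (is.null(table)) table <- syntheticMeanDispersionTable(nGenes, seed)
  if (nrow(table) == 0L) stop("empty mean-dispersion table")
  nDE <- round(nGenes * pdeg)
  nAhigher <- round(nDE * pa)
  withSeed(seed + 1L, {
    idx <- sample.int(nrow(table), nGenes, replace = TRUE)
    mu <- table$mu[idx]
    phi <- table$phi[idx]
    dePos <- sample.int(nGenes, nDE)
    aPos <- dePos[sample.int(nDE, nAhigher)]
    isDE <- logical(nGenes); isDE[dePos] <- TRUE
    dirn <- integer(nGenes)
    dirn[dePos] <- -1L
    dirn[aPos] <- 1L
    fc <- rep(1, nGenes)
    fc[dePos] <- sampleFoldChanges(foldChange, nDE,
                                   seed = sample.int(.Machine$integer.max, 1))
    S <- nA + nB
    meanMat <- matrix(mu, nGenes, S)
    if (nDE > 0) {
      isA <- c(rep(TRUE, nA), rep(FALSE, nB))
      up <- matrix(FALSE, nGenes, S)
      up[dirn == 1L, isA] <- TRUE
      up[dirn == -1L, !isA] <- TRUE
      meanMat[up] <- (mu * fc)[row(meanMat)[up]]
    }
    phiMat <- matrix(phi, nGenes, S)
    cnt <- matrix(0, nGenes, S)
    pois <- phiMat == 0
    if (any(pois)) cnt[pois] <- rpois(sum(pois), meanMat[pois])
    if (any(!pois)) cnt[!pois] <- rnbinom(sum(!pois), mu = meanMat[!pois],
                                          size = 1 / phiMat[!pois])
    rownames(cnt) <- sprintf("gene_%05d", seq_len(nGenes))
    colnames(cnt) <- c(sprintf("A_%d", seq_len(nA)),
                       sprintf("B_%d", seq_len(nB)))
    tcs <- TagCountSet(cnt, groups = rep(c("A", "B"), c(nA, nB)))
    SummarizedExperiment::rowData(tcs)$isDE <- isDE
    SummarizedExperiment::rowData(tcs)$direction <- dirn
    SummarizedExperiment::rowData(tcs)$foldChange <- fc
    SummarizedExperiment::rowData(tcs)$mu <- mu
    SummarizedExperiment::rowData(tcs)$phi <- phi
    S4Vectors::metadata(tcs)$simParams <- list(
      nGenes = nGenes, nA = nA, nB = nB, pdeg = pdeg, pa = pa,
      foldChange = foldChange, seed = seed)
    tcs
  })
}
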