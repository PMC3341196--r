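# Empirical-Bayes NB detector: per-gene posterior probability of differential
# expression under a two-component mixture (no-DE vs DE) whose NB parameters
# are an empirical prior bootstrapped from the data. The converged mixture
# weight is the objective estimate of the proportion of DEGs that drives the
# elimination step of the TbT pipeline.

# Vectorized per-row (mu, phi) ML fits of NB observations. The mean MLE is
# the (per-group) row mean for any phi; phi is fit by golden section on
# log phi, with the method-of-moments value as a fallback and phi = 0 whenever
# the pooled within-fit variance does not exceed the mean. `groupList` gives
# the column sets that share a mean: one set = iid fit (no-DE component), two
# sets = per-group means with a shared within-group dispersion (the ML fit of
# the DE model to that row, far more stable than fitting phi on each 3-sample
# group alone). Row means are floored at `muFloor` counts so that a gene
# silent in one group keeps a positive mean.
fitNBRows <- function(y, groupList = list(seq_len(ncol(y))), muFloor = 0.5) {
  mus <- lapply(groupList, function(sel)
    pmax(rowMeans(y[, sel, drop = FALSE]), muFloor))
  # pooled within-group moment estimate of overdispersion
  ss <- 0; mw <- 0; df <- 0
  for (i in seq_along(groupList)) {
    sel <- groupList[[i]]
    dev <- y[, sel, drop = FALSE] - mus[[i]]
    ss <- ss + rowSums(dev^2)
    mw <- mw + length(sel) * mus[[i]]
    df <- df + length(sel)
  }
  v <- ss / (df - length(groupList))
  mbar <- mw / df
  phi <- numeric(nrow(y))
  over <- v > mbar
  if (any(over)) {
    obj <- function(logPhi) {
      ph <- exp(logPhi)
      ll <- numeric(sum(over))
      for (i in seq_along(groupList))
        for (j in groupList[[i]])
          ll <- ll + nbLogDensity(y[over, j], mus[[i]][over], ph)
      ll
    }
    est <- tryCatch(exp(goldenSectionMax(obj, rep(log(1e-6), sum(over)),
                                         rep(log(10), sum(over)), tol = 1e-4)),
                    error = function(e)
                      pmax((v[over] - mbar[over]) / mbar[over]^2, 0))
    phi[over] <- pmax(est, 0)
  }
  c(mus, list(phi = phi))
}

#' Bootstrap an empirical NB prior from the data
#'
#' Samples \code{nBootstrap} genes with replacement (all-zero genes are
#' resampled, with a retry cap of 10 * nBootstrap) and fits NB parameters by
#' per-gene maximum likelihood on counts rescaled to the geometric-mean
#' effective library size: a pooled fit over all samples (no-DE component) and
#' per-group fits (DE component). Stored means are per unit effective library
#' size.
#'
#' @param x a \linkS4class{TagCountSet} (for the TbT pipeline: RPM-scaled and
#'   rounded).
#' @param effectiveSizes per-sample effective library sizes on the same scale
#'   as the counts.
#' @param nBootstrap number of bootstrap particles (>= 100; 2000 is a
#'   simulation-scale default, 10000 suits large real datasets).
#' @param seed integer seed (mandatory).
#' @param weightsNDE,weightsDE optional per-gene resampling weights for the
#'   no-DE and DE pools (used by the posterior-weighted prior refinement;
#'   uniform over non-zero genes when NULL).
#' @return a \linkS4class{PriorParticles}.
#' @export
bootstrapPriors <- function(x, effectiveSizes = libSizes(x),
                            nBootstrap = 2000L, seed,
                            weightsNDE = NULL, weightsDE = NULL) {
  stopifnot(nBootstrap >= 100L)
  cnt <- counts(x)
  G <- nrow(cnt)
  nonZero <- rowSums(cnt) > 0
  if (!any(nonZero)) stop("all genes are zero; cannot bootstrap a prior")
  drawPool <- function(weights, offset) {
    if (!is.null(weights)) {
      w <- weights * nonZero
      if (sum(w) <= 0) w <- as.numeric(nonZero)
      return(withSeed(seed + offset,
                      sample.int(G, nBootstrap, replace = TRUE,
                                 prob = w / sum(w))))
    }
    withSeed(seed + offset, {
      out <- integer(0)
      tries <- 0L
      while (length(out) < nBootstrap) {
        draw <- sample.int(G, nBootstrap - length(out), replace = TRUE)
        out <- c(out, draw[nonZero[draw]])
        tries <- tries + length(draw)
        if (tries > 10L * nBootstrap)
          stop("too many all-zero genes: bootstrap retry cap exceeded")
      }
      out
    })
  }
  idxN <- drawPool(weightsNDE, 0L)
  idxD <- if (is.null(weightsNDE) && is.null(weightsDE)) idxN
          else drawPool(weightsDE, 1L)
  nbar <- geomean(effectiveSizes)
  grp <- groups(x)
  isA <- grp == levels(grp)[1L]
  scaledN <- sweep(cnt[idxN, , drop = FALSE], 2L, nbar / effectiveSizes, "*")
  scaledD <- sweep(cnt[idxD, , drop = FALSE], 2L, nbar / effectiveSizes, "*")
  pooled <- fitNBRows(scaledN)
  grouped <- fitNBRows(scaledD, groupList = list(which(isA), which(!isA)))
  new("PriorParticles",
      mu = pooled[[1L]] / nbar, phi = pooled$phi,
      muA = grouped[[1L]] / nbar, phiA = grouped$phi,
      muB = grouped[[2L]] / nbar, phiB = grouped$phi,
      nBootstrap = as.integer(nBootstrap), seed = as.integer(seed))
}

#' Marginal likelihoods of the no-DE and DE models
#'
#' For each gene, averages over bootstrap particles of the NB likelihood of
#' all counts (no-DE: one pooled (mu, phi) for both groups) and, for the DE
#' model, the average over particle pairs of the product of per-group
#' likelihoods. Because the DE prior draws the two group means independently,
#' that pair average factorizes exactly into (mean over particles of the
#' A-group likelihood) x (mean of the B-group likelihood), i.e. all
#' nBootstrap^2 pairs contribute at linear cost. Everything is computed in log
#' space with log-sum-exp; genes for which every particle has zero likelihood
#' under both models are flagged uninformative.
#'
#' With \code{pairing = "paired"} the DE average instead runs over same-index
#' particle pairs (each particle's own A-fit with its own B-fit). That variant
#' is only meaningful once the DE pool has been enriched for likely DEGs
#' (posterior-weighted refinement): its pairs then sit on the fold-change
#' ridge of (muA, muB) space, which an independent product cannot represent.
#'
#' @param x a \linkS4class{TagCountSet} with integer counts.
#' @param effectiveSizes per-sample effective library sizes.
#' @param priors a \linkS4class{PriorParticles}.
#' @param pairing "independent" (factorized average over all particle pairs)
#'   or "paired" (same-index pairs).
#' @param chunkSize particles per block (memory bound).
#' @return a list with \code{logNDE}, \code{logDE} (per-gene log marginal
#'   likelihoods) and \code{uninformative} (logical).
#' @export
marginalLikelihoods <- function(x, effectiveSizes = libSizes(x), priors,
                                pairing = c("independent", "paired"),
                                chunkSize = 250L) {
  pairing <- match.arg(pairing)
  cnt <- counts(x)
  G <- nrow(cnt)
  grp <- groups(x)
  isA <- which(grp == levels(grp)[1L])
  isB <- which(grp != levels(grp)[1L])
  P <- priors@nBootstrap
  accumulate <- function(perParticle) {
    # streaming log-mean-exp over particles, chunked
    runMax <- rep(-Inf, G)
    runSum <- numeric(G)
    for (start in seq(1L, P, by = chunkSize)) {
      pr <- start:min(start + chunkSize - 1L, P)
      block <- perParticle(pr)                      # G x length(pr)
      bmax <- apply(block, 1L, max)
      newMax <- pmax(runMax, bmax)
      adj <- ifelse(is.finite(runMax), exp(runMax - newMax), 0)
      runSum <- runSum * adj +
        rowSums(exp(block - ifelse(is.finite(newMax), newMax, 0)))
      runMax <- newMax
    }
    out <- runMax + log(runSum / P)
    out[!is.finite(runMax)] <- -Inf
    out
  }
  ndeBlock <- function(pr) {
    block <- matrix(0, G, length(pr))
    for (j in seq_along(pr)) {
      p <- pr[j]
      ll <- numeric(G)
      for (k in seq_len(ncol(cnt)))
        ll <- ll + nbLogDensity(cnt[, k], priors@mu[p] * effectiveSizes[k],
                                priors@phi[p])
      block[, j] <- ll
    }
    block
  }
  groupBlock <- function(cols, mus, phis) function(pr) {
    block <- matrix(0, G, length(pr))
    for (j in seq_along(pr)) {
      p <- pr[j]
      ll <- numeric(G)
      for (k in cols)
        ll <- ll + nbLogDensity(cnt[, k], mus[p] * effectiveSizes[k], phis[p])
      block[, j] <- ll
    }
    block
  }
  logNDE <- accumulate(ndeBlock)
  logDE <- if (pairing == "independent") {
    accumulate(groupBlock(isA, priors@muA, priors@phiA)) +
      accumulate(groupBlock(isB, priors@muB, priors@phiB))
  } else {
    blockA <- groupBlock(isA, priors@muA, priors@phiA)
    blockB <- groupBlock(isB, priors@muB, priors@phiB)
    accumulate(function(pr) blockA(pr) + blockB(pr))
  }
  list(logNDE = logNDE, logDE = logDE,
       uninformative = !is.finite(logNDE) & !is.finite(logDE))
}

#' Estimate posterior DE probabilities and the DEG proportion
#'
#' Fixed-point iteration on the mixture weight p: posterior_g =
#' p L_DE / (p L_DE + (1 - p) L_NDE), then p <- mean(posterior), until
#' |delta p| < tol. The converged p is the estimated proportion of DEGs.
#' Uninformative genes sit at the model prior p.
#'
#' @param ml output of \code{\link{marginalLikelihoods}}.
#' @param pInit initial mixture weight (default 0.05).
#' @param tol convergence tolerance on p.
#' @param maxIter iteration cap; non-convergence returns the last iterate with
#'   \code{converged = FALSE} and a warning.
#' @return a \linkS4class{DEGSetEstimate} with \code{posteriorDE} and
#'   \code{pdegHat} filled (no flags yet; see
#'   \code{\link{identifyPotentialDEGs}}).
#' @export
estimatePosteriors <- function(ml, pInit = 0.05, tol = 1e-6,
                               maxIter = 1000L) {
  logRatio <- ml$logNDE - ml$logDE           # log(L_NDE / L_DE)
  logRatio[ml$uninformative] <- 0
  p <- pInit
  converged <- FALSE
  iter <- 0L
  post <- rep(p, length(logRatio))
  for (iter in seq_len(maxIter)) {
    post <- 1 / (1 + exp(log((1 - p) / p) + logRatio))
    post[ml$uninformative] <- p
    pNew <- mean(post)
    if (abs(pNew - p) < tol) {
      p <- pNew
      converged <- TRUE
      break
    }
    p <- pNew
  }
  if (!converged)
    warning("posterior fixed point did not converge in ", maxIter,
            " iterations")
  new("DEGSetEstimate", posteriorDE = post, pdegHat = p, paHat = 0.5,
      degFlags = logical(0), direction = integer(0),
      converged = converged, nIter = iter)
}

#' Flag potential DEGs and estimate the directional bias
#'
#' Flags the top round(pdegHat * G) genes by posterior DE probability (ties by
#' gene index). Direction compares effective-size-normalized group means
#' (+1 when higher in group A). paHat is the fraction of flagged genes that
#' are A-higher; with an empty flag set it is reported as 0.5 by convention.
#'
#' @param est a \linkS4class{DEGSetEstimate} from
#'   \code{\link{estimatePosteriors}}.
#' @param x the \linkS4class{TagCountSet} the posteriors were computed on.
#' @param effectiveSizes per-sample effective library sizes.
#' @return the completed \linkS4class{DEGSetEstimate}.
#' @export
identifyPotentialDEGs <- function(est, x, effectiveSizes = libSizes(x)) {
  G <- length(est@posteriorDE)
  stopifnot(G == nrow(x))
  nFlag <- round(est@pdegHat * G)
  flags <- logical(G)
  if (nFlag > 0) {
    ord <- order(-est@posteriorDE, seq_len(G))
    flags[ord[seq_len(nFlag)]] <- TRUE
  }
  y <- sweep(counts(x), 2L, effectiveSizes, "/")
  grp <- groups(x)
  isA <- grp == levels(grp)[1L]
  meanA <- rowMeans(y[, isA, drop = FALSE])
  meanB <- rowMeans(y[, !isA, drop = FALSE])
  dirn <- ifelse(meanA >= meanB, 1L, -1L)
  pa <- if (nFlag > 0) mean(dirn[flags] == 1L) else 0.5
  new("DEGSetEstimate", posteriorDE = est@posteriorDE, pdegHat = est@pdegHat,
      paHat = pa, degFlags = flags, direction = as.integer(dirn),
      converged = est@converged, nIter = est@nIter)
}

#' Run the full empirical-Bayes detector
#'
#' Convenience wrapper: RPM-scales the raw counts (rounding half-to-even to
#' integers, since the NB likelihood is evaluated on integer counts), rescales
#' the supplied normalization factors to the RPM column totals (effective size
#' 1e6 * factor), bootstraps the prior and returns the completed estimate.
#' RPM input is used because it empirically improves this detector's ranking
#' performance.
#'
#' With \code{nRefine >= 1} (default 1) the empirical prior is refined after a
#' first posterior pass: the no-DE pool is re-bootstrapped with weights
#' 1 - posterior, purging it of differential genes whose pooled fits carry
#' artificially inflated dispersions (those contaminated particles let the
#' no-DE model explain genuinely differential genes and depress the DEG
#' proportion estimate). The DE pool deliberately stays uniform:
#' posterior-weighting it feeds any residual normalization bias back into the
#' prior's fold-change structure and makes the elimination overshoot. This
#' mirrors the iterative bootstrap reweighting of empirical-Bayes count
#' detectors.
#'
#' @param x a raw-count \linkS4class{TagCountSet}.
#' @param factors per-sample normalization factors (geometric mean 1), e.g.
#'   from \code{\link{tmmFactors}}.
#' @param nBootstrap bootstrap particles.
#' @param seed integer seed.
#' @param pInit initial mixture weight.
#' @param nRefine posterior-weighted prior refinement rounds (0 = none).
#' @return a list with \code{estimate} (a \linkS4class{DEGSetEstimate}) and
#'   \code{ranking} (a \linkS4class{RankedList} by descending posterior).
#' @export
ebayesDetect <- function(x, factors = rep(1, ncol(x)), nBootstrap = 2000L,
                         seed, pInit = 0.05, nRefine = 1L) {
  rpm <- rpmScale(x)
  cntR <- round(counts(rpm))
  xr <- TagCountSet(cntR, groups = groups(x), libSizes = rep(1e6, ncol(x)))
  eff <- 1e6 * factors / geomean(factors)
  priors <- bootstrapPriors(xr, eff, nBootstrap = nBootstrap, seed = seed)
  ml <- marginalLikelihoods(xr, eff, priors)
  est <- estimatePosteriors(ml, pInit = pInit)
  for (r in seq_len(nRefine)) {
    post <- est@posteriorDE
    priors <- bootstrapPriors(xr, eff, nBootstrap = nBootstrap,
                              seed = seed + 100L * r,
                              weightsNDE = 1 - post)
    ml <- marginalLikelihoods(xr, eff, priors)
    est <- estimatePosteriors(ml, pInit = pInit)
  }
  est <- identifyPotentialDEGs(est, xr, eff)
  ranking <- RankedList(setNames(est@posteriorDE, rownames(x)),
                        direction = est@direction, higherIsBetter = TRUE,
                        method = "ebayes")
  list(estimate = est, ranking = ranking)
}
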