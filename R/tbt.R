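# The DEG-elimination normalization pipeline: TMM -> empirical-Bayes DEG
# identification -> TMM on the DEG-free submatrix, with the final factors
# rescaled by the library-size ratio before/after elimination.

# Steps 2b-3 of the pipeline given the step-1 result and the completed DEG
# estimate. Separated out so the formula identity (zero flags => TbT factors
# equal step-1 factors) is testable in isolation.
tbtFromFlags <- function(x, step1, est, trimM = 0.30, trimA = 0.05,
                         iteration = 0L) {
  flags <- est@degFlags
  if (all(flags)) stop("elimination emptied the matrix: every gene flagged")
  sub <- x[!flags, ]
  step3 <- tmmFactors(sub, trimM = trimM, trimA = trimA)
  libBefore <- colSums(counts(x))
  libAfter <- colSums(counts(sub))
  raw <- step3@factors * libAfter / libBefore
  tbt <- NormalizationResult(raw / geomean(raw), libSizes(x),
                             method = if (iteration == 0L) "tbt"
                                      else sprintf("tbt%d", iteration),
                             refSample = step3@refSample)
  new("TbTResult", step1 = step1, step2 = est, step3 = step3, tbt = tbt,
      eliminated = rownames(x)[flags], iteration = as.integer(iteration))
}

#' Three-step DEG-elimination (TbT) normalization
#'
#' Step 1: temporary TMM normalization of the raw counts. Step 2: potential
#' DEGs are identified on RPM-scaled data with the step-1 effective library
#' sizes, using the empirical-Bayes detector by default (the NB exact test is
#' available as an alternative detector). Step 3: TMM factors are recomputed
#' on the raw counts restricted to non-flagged genes; the final factors are
#' (step-3 factors) x (library sizes after elimination) / (library sizes
#' before elimination), rescaled to geometric mean 1 so they remain comparable
#' with plain TMM factors. When step 2 flags nothing the formula collapses and
#' the result equals step 1 exactly.
#'
#' @param x a raw-count \linkS4class{TagCountSet}.
#' @param trimM,trimA TMM trim fractions per side (steps 1 and 3).
#' @param nBootstrap bootstrap particles for the prior (step 2).
#' @param seed integer seed for the bootstrap.
#' @param detector "ebayes" (default) or "nbexact" for step 2. The exact-test
#'   detector flags the same number of genes as its estimated DEG proportion
#'   would (posterior surrogate: 1 - p).
#' @param pInit initial mixture weight of the detector.
#' @param nRefine posterior-weighted prior refinement rounds in the detector.
#' @return a \linkS4class{TbTResult}.
#' @examples
#' sim <- simulateCounts(nGenes = 300, pdeg = 0.2, pa = 0.9, seed = 11)
#' res <- runTbT(sim, nBootstrap = 100, seed = 1)
#' tbtFactors(res)
#' @export
runTbT <- function(x, trimM = 0.30, trimA = 0.05, nBootstrap = 2000L, seed,
                   detector = c("ebayes", "nbexact"), pInit = 0.05,
                   nRefine = 1L) {
  detector <- match.arg(detector)
  step1 <- tmmFactors(x, trimM = trimM, trimA = trimA)
  est <- detectStep2(x, step1@factors, nBootstrap, seed, detector, pInit,
                     nRefine)
  tbtFromFlags(x, step1, est, trimM = trimM, trimA = trimA, iteration = 0L)
}

# Step-2 detector dispatch on a given set of factors.
detectStep2 <- function(x, factors, nBootstrap, seed, detector, pInit,
                        nRefine = 1L) {
  if (detector == "ebayes")
    return(ebayesDetect(x, factors, nBootstrap = nBootstrap, seed = seed,
                        pInit = pInit, nRefine = nRefine)$estimate)
  # exact-test detector: 1 - p serves as the DE score; the flagged proportion
  # is the fraction of genes with p below 0.05 (the mixture-weight machinery
  # applies only to the empirical-Bayes likelihoods).
  eff <- libSizes(x) * factors / geomean(factors)
  rl <- exactNBTest(x, eff)
  pdeg <- mean(scores(rl) < 0.05)
  est <- new("DEGSetEstimate", posteriorDE = 1 - scores(rl),
             pdegHat = pdeg, paHat = 0.5, degFlags = logical(0),
             direction = integer(0), converged = TRUE, nIter = 0L)
  identifyPotentialDEGs(est, x, eff)
}

#' Iterative DEG-elimination normalization
#'
#' Round 0 is the original pipeline; each later round reruns the step-2
#' detector with the previous round's TbT effective library sizes and then
#' recomputes step 3, labelling the results TbT, TbT1, TbT2, ... Iteration
#' stops early once the largest per-sample |log2 factor change| drops below
#' \code{tol}; at that fixed point a further round reproduces the factors.
#'
#' @param x a raw-count \linkS4class{TagCountSet}.
#' @param nIterations refinement rounds after the original run (default 3).
#' @param tol early-stop tolerance on log2 factors (default 1e-3).
#' @inheritParams runTbT
#' @return a list of \linkS4class{TbTResult}, one per completed round.
#' @export
iterateTbT <- function(x, nIterations = 3L, trimM = 0.30, trimA = 0.05,
                       nBootstrap = 2000L, seed,
                       detector = c("ebayes", "nbexact"), pInit = 0.05,
                       nRefine = 1L, tol = 1e-3) {
  stopifnot(nIterations >= 0L)
  detector <- match.arg(detector)
  res0 <- runTbT(x, trimM = trimM, trimA = trimA, nBootstrap = nBootstrap,
                 seed = seed, detector = detector, pInit = pInit,
                 nRefine = nRefine)
  out <- list(res0)
  prev <- res0
  for (i in seq_len(nIterations)) {
    est <- detectStep2(x, prev@tbt@factors, nBootstrap, seed + i, detector,
                       pInit, nRefine)
    resI <- tbtFromFlags(x, prev@step1, est, trimM = trimM, trimA = trimA,
                         iteration = i)
    out[[i + 1L]] <- resI
    if (max(abs(log2(resI@tbt@factors) - log2(prev@tbt@factors))) < tol) {
      prev <- resI
      break
    }
    prev <- resI
  }
  out
}
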