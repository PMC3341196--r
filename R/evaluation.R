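# Scoring of normalizer/ranker combinations against simulation truth.

#' Area under the ROC curve of a ranked gene list
#'
#' Mann-Whitney formulation: the fraction of (DE, non-DE) gene pairs in which
#' the DE gene is ranked better, with tied scores counted half. Invariant
#' under strictly monotone transforms of the scores.
#'
#' @param x a \linkS4class{RankedList}, or a numeric score vector (in which
#'   case \code{higherIsBetter} applies).
#' @param truth logical vector (or a \code{simTruth} DataFrame) marking the
#'   true DE genes.
#' @param higherIsBetter for numeric \code{x}: do large scores mean stronger
#'   DE evidence?
#' @return AUC in [0, 1].
#' @examples
#' rocAUC(c(3, 2, 1), truth = c(TRUE, TRUE, FALSE), higherIsBetter = TRUE)
#' @export
rocAUC <- function(x, truth, higherIsBetter = TRUE) {
  if (is(x, "RankedList")) {
    higherIsBetter <- x@higherIsBetter
    x <- x@scores
  }
  if (is(truth, "DataFrame") || is.data.frame(truth)) truth <- truth$isDE
  truth <- as.logical(truth)
  stopifnot(length(x) == length(truth))
  nPos <- sum(truth); nNeg <- sum(!truth)
  if (nPos == 0L || nNeg == 0L)
    stop("need at least one DE and one non-DE gene")
  s <- if (higherIsBetter) x else -x
  r <- rank(s)                       # average ranks give half-credit ties
  (sum(r[truth]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

#' Confusion metrics of a DEG assignment
#'
#' @param flags per-gene logical DEG calls.
#' @param truth per-gene logical truth (or a \code{simTruth} DataFrame).
#' @return a list with TP, FP, TN, FN, sensitivity = TP/(TP+FN), specificity =
#'   TN/(TN+FP) and accuracy = (TP+TN)/G.
#' @export
confusionStats <- function(flags, truth) {
  if (is(truth, "DataFrame") || is.data.frame(truth)) truth <- truth$isDE
  flags <- as.logical(flags); truth <- as.logical(truth)
  stopifnot(length(flags) == length(truth))
  tp <- sum(flags & truth); fp <- sum(flags & !truth)
  fn <- sum(!flags & truth); tn <- sum(!flags & !truth)
  list(TP = tp, FP = fp, TN = tn, FN = fn,
       sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
       accuracy = (tp + tn) / length(flags))
}

#' Median log ratio of the true non-DE genes
#'
#' The median M (B over A, log2) of genes that are truly not differentially
#' expressed, under a given normalization: the closer to zero, the better the
#' normalization recovered the non-DE baseline. Genes with an undefined M
#' (zero mean in a group) are excluded.
#'
#' @param x a \linkS4class{TagCountSet}.
#' @param norm a \linkS4class{NormalizationResult}.
#' @param truth logical non-DE indicator is \code{!truth}; pass the per-gene
#'   DE truth (or a \code{simTruth} DataFrame).
#' @return the signed median log2 ratio.
#' @export
medianNonDEM <- function(x, norm, truth) {
  if (is(truth, "DataFrame") || is.data.frame(truth)) truth <- truth$isDE
  ma <- maStats(x, norm)
  keep <- !as.logical(truth) & ma$defined
  if (!any(keep)) stop("no non-DE gene has a defined log ratio")
  median(ma$m[keep])
}

#' True-discovery curve
#'
#' For each cutoff k, the number of true positives among the k top-ranked
#' genes.
#'
#' @param x a \linkS4class{RankedList}.
#' @param truth per-gene logical truth (or a \code{simTruth} DataFrame).
#' @param ks cutoffs, within [1, G].
#' @return a \code{data.frame} with columns \code{k} and \code{truePositives}.
#' @export
trueDiscoveryCurve <- function(x, truth, ks) {
  if (is(truth, "DataFrame") || is.data.frame(truth)) truth <- truth$isDE
  truth <- as.logical(truth)
  stopifnot(all(ks >= 1), all(ks <= length(truth)))
  cum <- cumsum(truth[rankOrder(x)])
  data.frame(k = as.integer(ks), truePositives = cum[ks])
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact when the smaller sample has at most 10 observations and there are no
#' ties; otherwise the normal approximation with tie and continuity
#' correction.
#'
#' @param x,y numeric samples.
#' @return the two-sided p-value.
#' @export
wilcoxonRankSum <- function(x, y) {
  stopifnot(length(x) > 0, length(y) > 0)
  ties <- anyDuplicated(c(x, y)) > 0
  useExact <- min(length(x), length(y)) <= 10 && !ties
  suppressWarnings(
    wilcox.test(x, y, alternative = "two.sided", exact = useExact,
                correct = TRUE)$p.value)
}

#' Benchmark TbT against plain TMM on simulated data
#'
#' Runs \code{nTrials} independent rounds of simulate -> normalize (TMM and
#' TbT) -> rank (NB exact test under each set of factors) -> score, and
#' returns one row per trial with the AUCs, the median non-DE log ratios under
#' both normalizations, and the TbT step-2 estimates with their confusion
#' metrics against the truth.
#'
#' @param nTrials number of simulation trials.
#' @param nGenes genes per trial.
#' @param pdeg,pa true DEG proportion and directional bias.
#' @param foldChange fold-change model.
#' @param nBootstrap bootstrap particles for the detector.
#' @param seed integer seed; trial t uses seed + t for every stochastic stage.
#' @param dispersion dispersion mode for the exact-test ranker.
#' @param nRefine prior refinement rounds in the step-2 detector.
#' @return a \code{data.frame} with columns \code{trial}, \code{aucTbT},
#'   \code{aucTMM}, \code{medianMTbT}, \code{medianMTMM}, \code{pdegHat},
#'   \code{paHat}, \code{sensitivity}, \code{specificity}, \code{accuracy}.
#' @export
benchmarkTbT <- function(nTrials = 10L, nGenes = 5000L, pdeg = 0.20,
                         pa = 0.90, foldChange = fixedFoldChange(4),
                         nBootstrap = 500L, seed, dispersion = "tagwise",
                         nRefine = 1L) {
  rows <- lapply(seq_len(nTrials), function(t) {
    s <- seed + t
    sim <- simulateCounts(nGenes = nGenes, pdeg = pdeg, pa = pa,
                          foldChange = foldChange, seed = s)
    truth <- simTruth(sim)
    res <- runTbT(sim, nBootstrap = nBootstrap, seed = s, nRefine = nRefine)
    tmm <- res@step1
    tbt <- res@tbt
    rankTbT <- exactNBTest(sim, effectiveLibSizes(tbt),
                           dispersion = dispersion)
    rankTMM <- exactNBTest(sim, effectiveLibSizes(tmm),
                           dispersion = dispersion)
    conf <- confusionStats(degFlags(res@step2), truth)
    data.frame(trial = t,
               aucTbT = rocAUC(rankTbT, truth),
               aucTMM = rocAUC(rankTMM, truth),
               medianMTbT = medianNonDEM(sim, tbt, truth),
               medianMTMM = medianNonDEM(sim, tmm, truth),
               pdegHat = pdegHat(res@step2),
               paHat = paHat(res@step2),
               sensitivity = conf$sensitivity,
               specificity = conf$specificity,
               accuracy = conf$accuracy)
  })
  do.call(rbind, rows)
}
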