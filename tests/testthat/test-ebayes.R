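# Detector tests run on RPM-scale inputs (integer counts with per-sample
# effective sizes), mirroring how the pipeline calls these functions.

rpmFixture <- function(sim) {
  cntR <- round(counts(rpmScale(sim)))
  TagCountSet(cntR, groups = groups(sim), libSizes = rep(1e6, ncol(sim)))
}

test_that("bootstrap priors are deterministic and respect degenerate input", {
  m <- matrix(rep(c(5, 8, 6, 9, 7, 6), each = 40), 40, 6, byrow = FALSE)
  tcs <- TagCountSet(m, rep(c("A", "B"), each = 3))
  pp <- bootstrapPriors(tcs, nBootstrap = 100, seed = 3)
  pp2 <- bootstrapPriors(tcs, nBootstrap = 100, seed = 3)
  expect_identical(pp@mu, pp2@mu)
  expect_identical(pp@phi, pp2@phi)
  expect_identical(pp@muA, pp2@muA)
  # every gene identical: one particle value repeated
  expect_equal(length(unique(pp@mu)), 1L)
  expect_true(all(pp@mu > 0) && all(pp@phi >= 0))

  expect_error(bootstrapPriors(TagCountSet(matrix(0, 5, 2) + 0, c("A", "B"),
                                           libSizes = c(1, 1)),
                               nBootstrap = 100, seed = 1), "zero")
})

test_that("bootstrap particle means recover the generating distribution", {
  sim <- simulateCounts(nGenes = 4000, pdeg = 0, pa = 0.5, seed = 15)
  xr <- rpmFixture(sim)
  eff <- rep(1e6, 6)
  pp <- bootstrapPriors(xr, eff, nBootstrap = 2000, seed = 2)
  # compare fitted particle means (per unit effective size, scaled back up)
  # against the generator's mean distribution, on the RPM scale
  scale <- 1e6 / mean(libSizes(sim))
  muGen <- SummarizedExperiment::rowData(sim)$mu * scale
  ks <- suppressWarnings(ks.test(pp@mu * 1e6, muGen))
  expect_gt(ks$p.value, 0.01)
})

test_that("marginal likelihoods match a hand-computed two-particle prior", {
  cnt <- matrix(c(2, 2, 8, 8), 1, 4)
  tcs <- TagCountSet(cnt, c("A", "A", "B", "B"), libSizes = rep(10, 4))
  pp <- new("PriorParticles",
            mu = c(0.2, 0.5), phi = c(0, 0.1),
            muA = c(0.2, 0.3), phiA = c(0, 0.1),
            muB = c(0.8, 0.6), phiB = c(0.05, 0),
            nBootstrap = 2L, seed = 1L)
  ml <- marginalLikelihoods(tcs, rep(10, 4), pp)
  nbll <- function(y, mu, phi) {
    if (phi == 0) return(sum(dpois(y, mu, log = TRUE)))
    sum(dnbinom(y, mu = mu, size = 1 / phi, log = TRUE))
  }
  byHand <- function(mus, phis, y) {
    vals <- vapply(seq_along(mus),
                   function(p) nbll(y, mus[p] * 10, phis[p]), numeric(1))
    log(mean(exp(vals)))
  }
  expect_equal(ml$logNDE, byHand(pp@mu, pp@phi, c(2, 2, 8, 8)),
               tolerance = 1e-10)
  expect_equal(ml$logDE,
               byHand(pp@muA, pp@phiA, c(2, 2)) +
                 byHand(pp@muB, pp@phiB, c(8, 8)),
               tolerance = 1e-10)
})

test_that("a flat gene never favours the DE model under symmetric priors", {
  cnt <- matrix(6, 1, 6)
  tcs <- TagCountSet(cnt, rep(c("A", "B"), each = 3), libSizes = rep(10, 6))
  pp <- new("PriorParticles",
            mu = c(0.4, 0.6, 0.8), phi = c(0.1, 0.1, 0.1),
            muA = c(0.4, 0.6, 0.8), phiA = c(0.1, 0.1, 0.1),
            muB = c(0.4, 0.6, 0.8), phiB = c(0.1, 0.1, 0.1),
            nBootstrap = 3L, seed = 1L)
  ml <- marginalLikelihoods(tcs, rep(10, 6), pp)
  expect_gte(ml$logNDE, ml$logDE)
})

test_that("posterior fixed point: uninformative and two-gene oracle cases", {
  # equal likelihoods: pInit is a fixed point and every posterior equals it
  ml <- list(logNDE = rep(-5, 10), logDE = rep(-5, 10),
             uninformative = rep(FALSE, 10))
  est <- estimatePosteriors(ml, pInit = 0.05)
  expect_equal(pdegHat(est), 0.05, tolerance = 1e-9)
  expect_equal(posteriorDE(est), rep(0.05, 10), tolerance = 1e-9)

  # two genes with likelihood ratios 9 and 1/9: independent scalar iteration
  ml2 <- list(logNDE = c(0, log(9)), logDE = c(log(9), 0),
              uninformative = rep(FALSE, 2))
  est2 <- estimatePosteriors(ml2, pInit = 0.5)
  p <- 0.5
  for (i in 1:10000) {
    post <- c(9 * p / (9 * p + (1 - p)), p / (p + 9 * (1 - p)))
    pNew <- mean(post)
    if (abs(pNew - p) < 1e-12) break
    p <- pNew
  }
  expect_equal(pdegHat(est2), p, tolerance = 1e-5)
  # fixed-point identity: mean posterior equals pdegHat
  expect_equal(mean(posteriorDE(est2)), pdegHat(est2), tolerance = 1e-6)
})

test_that("flag selection honours the rounding rule and boundary", {
  est0 <- new("DEGSetEstimate", posteriorDE = runif(10), pdegHat = 0,
              paHat = 0.5, degFlags = logical(0), direction = integer(0),
              converged = TRUE, nIter = 1L)
  tcs <- makeCounts(G = 10, seed = 4)
  out0 <- identifyPotentialDEGs(est0, tcs)
  expect_identical(sum(degFlags(out0)), 0L)
  expect_equal(paHat(out0), 0.5)

  est25 <- new("DEGSetEstimate", posteriorDE = seq(0, 1, length.out = 10),
               pdegHat = 0.25, paHat = 0.5, degFlags = logical(0),
               direction = integer(0), converged = TRUE, nIter = 1L)
  out25 <- identifyPotentialDEGs(est25, tcs)
  expect_identical(sum(degFlags(out25)), as.integer(round(0.25 * 10)))
  # the flagged genes are the top posteriors
  expect_true(all(which(degFlags(out25)) %in% order(-posteriorDE(est25))[1:2]))
})

test_that("pdegHat recovers the DEG proportion at simulation scale", {
  sim <- simulateCounts(nGenes = 5000, pdeg = 0.2, pa = 0.5, seed = 23)
  det <- ebayesDetect(sim, normFactors(tmmFactors(sim)), nBootstrap = 500,
                      seed = 23)
  expect_gte(pdegHat(det$estimate), 0.12)
  expect_lte(pdegHat(det$estimate), 0.25)
})

test_that("directional bias is recovered and label swap flips it", {
  sim <- simulateCounts(nGenes = 1500, pdeg = 0.2, pa = 0.9, seed = 31)
  det <- ebayesDetect(sim, nBootstrap = 200, seed = 31)
  expect_gt(paHat(det$estimate), 0.5)

  swapped <- TagCountSet(counts(sim)[, c(4:6, 1:3)],
                         groups = rep(c("A", "B"), each = 3))
  detS <- ebayesDetect(swapped, nBootstrap = 200, seed = 31)
  expect_equal(posteriorDE(detS$estimate), posteriorDE(det$estimate),
               tolerance = 1e-8)
  expect_equal(paHat(detS$estimate), 1 - paHat(det$estimate),
               tolerance = 1e-8)
  expect_true(all(posteriorDE(det$estimate) >= 0 &
                    posteriorDE(det$estimate) <= 1))
})

test_that("widening between-group separation never lowers the posterior", {
  base <- matrix(rep(c(20, 22, 18), 2), 1, 6)
  # dense grid prior so that coverage gaps cannot mask the monotonicity
  muGrid <- rep(exp(seq(log(0.002), log(0.2), length.out = 100)), each = 2)
  phiGrid <- rep(c(0.05, 0.3), 100)
  pp <- new("PriorParticles", mu = muGrid, phi = phiGrid,
            muA = muGrid, phiA = phiGrid, muB = muGrid, phiB = phiGrid,
            nBootstrap = 200L, seed = 1L)
  lr <- vapply(c(0, 4, 8, 14), function(d) {
    cnt <- base + rep(c(0, d), each = 3)
    tcs <- TagCountSet(cnt, rep(c("A", "B"), each = 3),
                       libSizes = rep(1000, 6))
    ml <- marginalLikelihoods(tcs, rep(1000, 6), pp)
    ml$logDE - ml$logNDE
  }, numeric(1))
  # the posterior is monotone in the likelihood ratio at any mixture weight
  expect_true(all(diff(lr) >= -1e-8))
})
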