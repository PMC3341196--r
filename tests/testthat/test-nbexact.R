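test_that("library equalization is mean-preserving and proportional", {
  tcs <- makeCounts(G = 30, seed = 2)
  # equal effective sizes: group sums are the raw sums
  eqS <- equalizeLibraries(tcs, rep(1000, 6))
  isA <- groups(tcs) == "A"
  expect_equal(eqS$sumA, rowSums(counts(tcs)[, isA]))

  # one sample at twice the depth contributes exactly half
  eff <- c(2, 1, 1, 1, 1, 1) * 5000
  eq2 <- equalizeLibraries(tcs, eff)
  nbar <- prod(eff)^(1 / 6)
  expect_equal(eq2$pseudo[, 1], counts(tcs)[, 1] * nbar / eff[1])

  # total adjusted count equals the independent arithmetic
  expect_equal(sum(eq2$pseudo),
               sum(sweep(counts(tcs), 2, nbar / eff, "*")))
})

test_that("common dispersion recovers the generating value", {
  # Poisson data: estimate collapses toward zero
  set.seed(41)
  m <- matrix(rpois(2000 * 6, lambda = 100), 2000, 6)
  tcs <- TagCountSet(m, rep(c("A", "B"), each = 3))
  est <- estimateCommonDispersion(tcs)
  expect_lte(est@common, 0.01)

  # NB data with phi = 0.2
  m2 <- matrix(rnbinom(2000 * 6, mu = 100, size = 5), 2000, 6)
  tcs2 <- TagCountSet(m2, rep(c("A", "B"), each = 3))
  est2 <- estimateCommonDispersion(tcs2)
  expect_gte(est2@common, 0.15)
  expect_lte(est2@common, 0.25)
})

test_that("a constant gene pulls the conditional likelihood toward phi = 0", {
  pseudo <- matrix(c(7, 7, 7, 7, 7, 7), 1, 6)
  isA <- rep(c(TRUE, FALSE), each = 3)
  ll <- vapply(c(1e-4, 0.01, 0.1, 1),
               function(p) tagnorm:::condLogLikMatrix(pseudo, isA, p),
               numeric(1))
  expect_true(all(diff(ll) < 0))
})

test_that("tagwise dispersion limits: infinite and zero prior weight", {
  tcs <- makeCounts(G = 80, mu = 60, size = 3, seed = 6)
  common <- estimateCommonDispersion(tcs)
  inf <- estimateTagwiseDispersion(tcs, common = common, priorWeight = Inf)
  expect_equal(inf@tagwise, rep(common@common, 80))

  # zero weight: each gene at its own conditional maximizer
  zero <- estimateTagwiseDispersion(tcs, common = common, priorWeight = 0)
  eq <- equalizeLibraries(tcs, libSizes(tcs))
  isA <- groups(tcs) == "A"
  for (g in c(1, 17, 55)) {
    own <- optimize(function(lp)
      tagnorm:::condLogLikMatrix(eq$pseudo[g, , drop = FALSE], isA, exp(lp)),
      interval = log(c(1e-6, 10)), maximum = TRUE, tol = 1e-5)
    expect_equal(log(zero@tagwise[g]), own$maximum, tolerance = 0.01)
  }

  # a large finite weight lands near the common value
  big <- estimateTagwiseDispersion(tcs, common = common, priorWeight = 1e5)
  expect_equal(log(big@tagwise), rep(log(common@common), 80),
               tolerance = 0.05)
})

test_that("tagwise dispersion separates a mixed-dispersion population", {
  set.seed(51)
  G <- 1000
  phiTrue <- rep(c(0.05, 0.5), each = G / 2)
  m <- matrix(rnbinom(G * 6, mu = 100, size = rep(1 / phiTrue, 6)), G, 6)
  tcs <- TagCountSet(m, rep(c("A", "B"), each = 3))
  tw <- estimateTagwiseDispersion(tcs)@tagwise
  medLow <- median(tw[seq_len(G / 2)])
  medHigh <- median(tw[G / 2 + seq_len(G / 2)])
  expect_lt(medLow, medHigh)

  # weakening the prior widens the separation toward the generating values
  tw2 <- estimateTagwiseDispersion(tcs, priorWeight = 2)@tagwise
  gap2 <- median(tw2[G / 2 + seq_len(G / 2)]) - median(tw2[seq_len(G / 2)])
  expect_gt(gap2, medHigh - medLow)
  expect_gt(gap2, 0.1)
})

test_that("exact NB p-values: symmetry, binomial limit, enumeration oracle", {
  # balanced observation is modal with a symmetric pmf: p = 1
  expect_equal(nbExactPValue(10, 20, 3, 3, 0.1), 1)
  # zero total is untestable by convention
  expect_equal(nbExactPValue(0, 0, 3, 3, 0.1), 1)

  # Poisson limit with one library per group: two-sided binomial(10, 1/2)
  f <- dbinom(0:10, 10, 0.5)
  oracle <- sum(f[f <= f[1] * (1 + 1e-12)])
  expect_equal(nbExactPValue(0, 10, 1, 1, 0), oracle)
  expect_equal(oracle, 2 / 1024)

  # general case against an independent dnbinom-product enumeration
  cases <- expand.grid(s = c(7, 23, 50), phi = c(0, 0.1, 1))
  for (i in seq_len(nrow(cases))) {
    s <- cases$s[i]; phi <- cases$phi[i]
    nA <- 3; nB <- 3
    lam <- s / (nA + nB)
    k <- 0:s
    fk <- if (phi == 0) dbinom(k, s, 0.5) else
      dnbinom(k, mu = nA * lam, size = nA / phi) *
        dnbinom(s - k, mu = nB * lam, size = nB / phi)
    fk <- fk / sum(fk)
    for (yA in c(0, floor(s / 4), floor(s / 2))) {
      expect_equal(nbExactPValue(yA, s, nA, nB, phi),
                   min(1, sum(fk[fk <= fk[yA + 1] * (1 + 1e-12)])),
                   tolerance = 1e-10)
    }
  }
})

test_that("conditional pmf normalizes and p is monotone from the mode", {
  for (phi in c(0, 0.2, 1)) {
    pmf <- tagnorm:::condPMF(30, 3, 2, phi)
    expect_equal(sum(pmf), 1, tolerance = 1e-10)
    p <- vapply(0:30, function(y) nbExactPValue(y, 30, 3, 2, phi), numeric(1))
    mode <- which.max(pmf) - 1
    expect_true(all(diff(p[seq_len(mode + 1)]) >= -1e-12))        # rising to mode
    expect_true(all(diff(p[(mode + 1):31]) <= 1e-12))             # falling after
  }
})

test_that("exact test ranking: label swap flips direction, not p-values", {
  tcs <- makeCounts(G = 60, seed = 13)
  rl <- exactNBTest(tcs, dispersion = "common")
  swapped <- TagCountSet(counts(tcs)[, c(4:6, 1:3)],
                         groups = rep(c("A", "B"), each = 3))
  rl2 <- exactNBTest(swapped, dispersion = "common")
  expect_equal(unname(scores(rl2)), unname(scores(rl)))
  nz <- direction(rl) != 0
  expect_equal(direction(rl2)[nz], -direction(rl)[nz])
  expect_true(all(scores(rl) > 0 & scores(rl) <= 1))
  # ascending order with index tie-break
  expect_identical(rankOrder(rl),
                   as.integer(order(scores(rl), seq_along(scores(rl)))))
})
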