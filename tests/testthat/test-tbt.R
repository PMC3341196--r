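test_that("an empty elimination set collapses TbT to the step-1 factors", {
  tcs <- makeCounts(G = 120, seed = 71)
  step1 <- tmmFactors(tcs)
  est <- new("DEGSetEstimate", posteriorDE = rep(0, 120), pdegHat = 0,
             paHat = 0.5, degFlags = rep(FALSE, 120),
             direction = rep(1L, 120), converged = TRUE, nIter = 1L)
  res <- tagnorm:::tbtFromFlags(tcs, step1, est)
  expect_equal(tbtFactors(res), normFactors(step1), tolerance = 1e-12)
  expect_length(res@eliminated, 0)

  # flagging everything empties the matrix
  estAll <- new("DEGSetEstimate", posteriorDE = rep(1, 120), pdegHat = 1,
                paHat = 0.5, degFlags = rep(TRUE, 120),
                direction = rep(1L, 120), converged = TRUE, nIter = 1L)
  expect_error(tagnorm:::tbtFromFlags(tcs, step1, estAll), "emptied")
})

test_that("TbT run is deterministic and keeps eliminated genes out of step 3", {
  sim <- simulateCounts(nGenes = 800, pdeg = 0.2, pa = 0.9, seed = 73)
  res <- runTbT(sim, nBootstrap = 150, seed = 73)
  res2 <- runTbT(sim, nBootstrap = 150, seed = 73)
  expect_identical(tbtFactors(res), tbtFactors(res2))
  expect_identical(res@eliminated, res2@eliminated)
  expect_length(res@eliminated, round(pdegHat(res@step2) * 800))

  # step 3 is exactly TMM on the submatrix without the eliminated genes
  sub <- sim[!rownames(sim) %in% res@eliminated, ]
  expect_equal(normFactors(res@step3), normFactors(tmmFactors(sub)))

  # TbT factor formula: step3 x library-size ratio, geometric mean 1
  ratio <- colSums(counts(sub)) / colSums(counts(sim))
  raw <- normFactors(res@step3) * ratio
  expect_equal(tbtFactors(res), raw / prod(raw)^(1 / length(raw)))
  expect_lt(abs(prod(tbtFactors(res))^(1 / 6) - 1), 1e-12)
})

test_that("under biased DE the TbT factors recentre the non-DE log ratios", {
  sim <- simulateCounts(nGenes = 5000, pdeg = 0.2, pa = 0.9, seed = 75)
  tr <- simTruth(sim)
  res <- runTbT(sim, nBootstrap = 300, seed = 75)
  expect_lt(abs(medianNonDEM(sim, res@tbt, tr)),
            abs(medianNonDEM(sim, res@step1, tr)))
  # estimated bias direction matches the truth (more A-higher flags)
  expect_gt(paHat(res@step2), 0.5)
})

test_that("without bias the TbT factors stay close to plain TMM", {
  sim <- simulateCounts(nGenes = 5000, pdeg = 0.2, pa = 0.5, seed = 77)
  res <- runTbT(sim, nBootstrap = 300, seed = 77)
  expect_equal(tbtFactors(res), normFactors(res@step1), tolerance = 0.02)
})

test_that("iteration relabels rounds and is idempotent at the fixed point", {
  sim <- simulateCounts(nGenes = 600, pdeg = 0.1, pa = 0.9, seed = 79)
  rounds <- iterateTbT(sim, nIterations = 2, nBootstrap = 150, seed = 79)
  expect_gte(length(rounds), 1)
  expect_identical(rounds[[1]]@iteration, 0L)
  for (i in seq_along(rounds))
    expect_identical(rounds[[i]]@iteration, i - 1L)

  # with a huge tolerance the first refinement round is accepted as converged
  early <- iterateTbT(sim, nIterations = 5, nBootstrap = 150, seed = 79,
                      tol = 10)
  expect_identical(length(early), 2L)
  # rerunning from the same state reproduces the factors bit for bit
  again <- iterateTbT(sim, nIterations = 5, nBootstrap = 150, seed = 79,
                      tol = 10)
  expect_identical(tbtFactors(early[[2]]), tbtFactors(again[[2]]))
})

test_that("iterated elimination helps under bias and is neutral without it", {
  nSeeds <- 10
  accGain <- matrix(NA_real_, nSeeds, 2)
  acc0unb <- acc3unb <- numeric(nSeeds)
  for (s in seq_len(nSeeds)) {
    simB <- simulateCounts(nGenes = 1200, pdeg = 0.2, pa = 0.9, seed = 400 + s)
    rB <- iterateTbT(simB, nIterations = 1, nBootstrap = 150, seed = 400 + s,
                     tol = 0)
    trB <- simTruth(simB)
    accGain[s, ] <- c(
      confusionStats(degFlags(rB[[1]]@step2), trB)$accuracy,
      confusionStats(degFlags(rB[[2]]@step2), trB)$accuracy)

    simU <- simulateCounts(nGenes = 1200, pdeg = 0.2, pa = 0.5, seed = 800 + s)
    rU <- iterateTbT(simU, nIterations = 3, nBootstrap = 150, seed = 800 + s,
                     tol = 0)
    trU <- simTruth(simU)
    acc0unb[s] <- confusionStats(degFlags(rU[[1]]@step2), trU)$accuracy
    acc3unb[s] <- confusionStats(degFlags(rU[[length(rU)]]@step2),
                                 trU)$accuracy
  }
  # biased case: refinement does not hurt the DEG assignment on average
  expect_gte(mean(accGain[, 2]), mean(accGain[, 1]))
  # unbiased case: rounds 0 and 3 statistically indistinguishable
  expect_gt(wilcoxonRankSum(acc0unb, acc3unb), 0.01)
})
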