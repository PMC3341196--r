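# Small fixture builders shared across test files.

# A deterministic NB count matrix wrapped as a TagCountSet.
makeCounts <- function(G = 50, nA = 3, nB = 3, mu = 50, size = 2, seed = 1,
                       shift = 1) {
  set.seed(seed)
  m <- matrix(rnbinom(G * (nA + nB), mu = mu, size = size) + shift, G, nA + nB)
  TagCountSet(m, groups = rep(c("A", "B"), c(nA, nB)))
}

# Independent reimplementation of the M-A statistics, gene by gene.
bruteMA <- function(cnt, libs, factors, isA) {
  eff <- libs * factors
  t(vapply(seq_len(nrow(cnt)), function(g) {
    y <- cnt[g, ] / eff
    mA <- mean(y[isA]); mB <- mean(y[!isA])
    if (mA > 0 && mB > 0) c(log2(mB / mA), (log2(mB) + log2(mA)) / 2)
    else c(NA_real_, NA_real_)
  }, numeric(2)))
}

# Independent reimplementation of the weighted doubly trimmed mean of M,
# by explicit sorting and masking.
bruteTMMPair <- function(obs, ref, No, Nr, trimM, trimA) {
  keep <- obs > 0 & ref > 0
  obs <- obs[keep]; ref <- ref[keep]
  M <- log2((obs / No) / (ref / Nr))
  A <- 0.5 * log2((obs / No) * (ref / Nr))
  w <- 1 / ((No - obs) / (No * obs) + (Nr - ref) / (Nr * ref))
  n <- length(M)
  loM <- floor(n * trimM) + 1; hiM <- n + 1 - loM
  loA <- floor(n * trimA) + 1; hiA <- n + 1 - loA
  sel <- rank(M) >= loM & rank(M) <= hiM & rank(A) >= loA & rank(A) <= hiA
  sum(w[sel] * M[sel]) / sum(w[sel])
}

# Exhaustive pairwise AUC: fraction of (DE, non-DE) pairs in which the DE
# gene scores better, ties half.
bruteAUC <- function(scores, truth, higherIsBetter = TRUE) {
  s <- if (higherIsBetter) scores else -scores
  pos <- s[truth]; neg <- s[!truth]
  tot <- 0
  for (p in pos) for (q in neg)
    tot <- tot + if (p > q) 1 else if (p == q) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# Exact two-sided Wilcoxon rank-sum p-value by enumeration of all
# choose(n, nx) assignments of ranks to the first sample.
bruteWilcoxon <- function(x, y) {
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  wObs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combs <- combn(nx + ny, nx)
  ws <- apply(combs, 2, function(idx) sum(r[idx])) - nx * (nx + 1) / 2
  mu <- nx * ny / 2
  mean(abs(ws - mu) >= abs(wObs - mu) - 1e-12)
}
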