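# Internal numerical helpers shared across modules.

# Geometric mean of strictly positive values.
geomean <- function(x) exp(mean(log(x)))

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards. All stochastic operations in the package
# funnel through this so that identical seeds give bit-identical output.
withSeed <- function(seed, expr) {
  seed <- as.integer(seed)
  if (is.na(seed)) stop("seed must be a finite integer")
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  expr
}

# Stream-safe log(sum(exp(x))) over matrix rows.
rowLogSumExp <- function(x) {
  m <- apply(x, 1L, max)
  out <- m + log(rowSums(exp(x - m)))
  # rows that are entirely -Inf stay -Inf (exp(-Inf - -Inf) = NaN otherwise)
  out[!is.finite(m)] <- -Inf
  out
}

# Negative-binomial log density with mean/dispersion parameterization,
# V = mu + phi * mu^2. phi = 0 is the Poisson limit. Supports fractional y
# (continuous extension via lgamma), which the dispersion fits need for
# depth-equalized pseudo-counts.
nbLogDensity <- function(y, mu, phi) {
  n <- max(length(y), length(mu), length(phi))
  y <- rep_len(y, n); mu <- rep_len(mu, n); phi <- rep_len(phi, n)
  out <- numeric(n)
  zero <- mu <= 0
  if (any(zero)) out[zero] <- ifelse(y[zero] == 0, 0, -Inf)
  pois <- !zero & phi <= 0
  if (any(pois))
    out[pois] <- y[pois] * log(mu[pois]) - mu[pois] - lgamma(y[pois] + 1)
  nb <- !zero & phi > 0
  if (any(nb)) {
    r <- 1 / phi[nb]
    yv <- y[nb]; mv <- mu[nb]
    out[nb] <- lgamma(yv + r) - lgamma(r) - lgamma(yv + 1) +
      yv * (log(mv) - log(r + mv)) - r * log1p(mv / r)
  }
  out
}

# Vectorized golden-section maximization over per-row intervals.
# f(x) must accept a vector with one value per row and return the objective
# per row. Used for per-gene/per-particle dispersion fits.
goldenSectionMax <- function(f, lower, upper, tol = 1e-4, maxIter = 100L) {
  gr <- (sqrt(5) - 1) / 2
  a <- lower; b <- upper
  x1 <- b - gr * (b - a)
  x2 <- a + gr * (b - a)
  f1 <- f(x1); f2 <- f(x2)
  for (i in seq_len(maxIter)) {
    if (all(b - a < tol)) break
    sel <- f1 < f2
    # move left bound where f1 < f2, right bound otherwise
    a <- ifelse(sel, x1, a)
    b <- ifelse(sel, b, x2)
    x1n <- ifelse(sel, x2, b - gr * (b - a))
    x2n <- ifelse(sel, a + gr * (b - a), x1)
    fOld1 <- f1; fOld2 <- f2
    x1 <- x1n; x2 <- x2n
    need1 <- sel          # x1 took old x2's value where sel
    f1 <- ifelse(sel, fOld2, NA_real_)
    f2 <- ifelse(sel, NA_real_, fOld1)
    miss1 <- is.na(f1); miss2 <- is.na(f2)
    if (any(miss1)) f1[miss1] <- f(x1)[miss1]
    if (any(miss2)) f2[miss2] <- f(x2)[miss2]
  }
  mid <- (a + b) / 2
  mid
}
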