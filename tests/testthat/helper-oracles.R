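# Independent reference implementations used to cross-check the package.
# Each is written directly from the published recipe of the statistic it
# checks and shares no code with the implementation under test.

# trimmed mean of M-values, trim 30% by M and 5% by A, inverse-variance
# weights, factors rescaled to geometric mean 1
tmmOracle <- function(cnt, refCol = NULL) {
  lib <- colSums(cnt)
  if (is.null(refCol)) {
    uq <- apply(cnt, 2, stats::quantile, probs = 0.75) / lib
    refCol <- which.min(abs(uq - mean(uq)))
  }
  ref <- cnt[, refCol]
  nR <- lib[refCol]
  f <- vapply(seq_len(ncol(cnt)), function(j) {
    obs <- cnt[, j]
    nO <- lib[j]
    ok <- obs > 0 & ref > 0
    o <- obs[ok]; r <- ref[ok]
    M <- log2((o / nO) / (r / nR))
    A <- (log2(o / nO) + log2(r / nR)) / 2
    v <- (nO - o) / (nO * o) + (nR - r) / (nR * r)
    if (max(abs(M)) < 1e-6) return(1)
    n <- length(M)
    loM <- floor(n * 0.3) + 1; hiM <- n + 1 - loM
    loA <- floor(n * 0.05) + 1; hiA <- n + 1 - loA
    keep <- rank(M) >= loM & rank(M) <= hiM &
      rank(A) >= loA & rank(A) <= hiA
    2^(sum(M[keep] / v[keep]) / sum(1 / v[keep]))
  }, numeric(1))
  f / exp(mean(log(f)))
}

# O(n^3) triple-loop topological overlap
tomOracle <- function(a) {
  n <- nrow(a)
  tom <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    l <- 0
    for (u in seq_len(n)) if (u != i && u != j) l <- l + a[i, u] * a[u, j]
    ki <- sum(a[i, -i]); kj <- sum(a[j, -j])
    tom[i, j] <- (l + a[i, j]) / (min(ki, kj) + 1 - a[i, j])
  }
  dimnames(tom) <- dimnames(a)
  tom
}

# naive UPGMA: repeatedly merge the closest pair, average-linkage update;
# returns sorted merge heights
upgmaHeightsOracle <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  size <- rep(1, n)
  active <- seq_len(n)
  heights <- numeric(0)
  while (length(active) > 1) {
    best <- c(NA, NA); bh <- Inf
    for (ii in seq_along(active)) for (jj in seq_along(active)) {
      if (jj <= ii) next
      i <- active[ii]; j <- active[jj]
      if (d[i, j] < bh) { bh <- d[i, j]; best <- c(i, j) }
    }
    i <- best[1]; j <- best[2]
    heights <- c(heights, bh)
    for (k in active) {
      if (k == i || k == j) next
      d[i, k] <- d[k, i] <-
        (size[i] * d[i, k] + size[j] * d[j, k]) / (size[i] + size[j])
    }
    size[i] <- size[i] + size[j]
    active <- setdiff(active, j)
  }
  sort(heights)
}

# classical MDS by explicit double-centering + eigendecomposition
mdsSpectralOracle <- function(d, k = 2) {
  d <- as.matrix(d)
  n <- nrow(d)
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (d^2) %*% J
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  pts <- e$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(pmax(e$values[seq_len(k)], 0)), k)
  list(points = pts, values = e$values)
}

# two-sample KS D by scanning the pooled CDF grid, p by an independent
# coding of the Kolmogorov series
ksOracle <- function(x, y) {
  grid <- sort(unique(c(x, y)))
  Dx <- vapply(grid, function(q) mean(x <= q), numeric(1))
  Dy <- vapply(grid, function(q) mean(y <= q), numeric(1))
  D <- max(abs(Dx - Dy))
  ne <- length(x) * length(y) / (length(x) + length(y))
  lam <- (sqrt(ne) + 0.12 + 0.11 / sqrt(ne)) * D
  s <- 0
  for (k in 1:100) s <- s + (-1)^(k - 1) * exp(-2 * k^2 * lam^2)
  list(D = D, p = if (D <= 0) 1 else min(1, max(0, 2 * s)))
}

# hypergeometric upper tail by exact log-PMF summation
hyperUpperOracle <- function(x, K, N, n) {
  supp <- max(0, n + K - N):min(n, K)
  lp <- lchoose(K, supp) + lchoose(N - K, n - supp) - lchoose(N, n)
  sum(exp(lp[supp >= x]))
}

# BH step-up from first principles
bhOracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  out <- numeric(m)
  out[o] <- pmin(q, 1)
  out
}

# adjusted Rand index between two labelings
ari <- function(a, b) {
  tab <- table(a, b)
  sum2 <- function(x) sum(choose(x, 2))
  sij <- sum2(tab)
  si <- sum2(rowSums(tab))
  sj <- sum2(colSums(tab))
  n2 <- choose(length(a), 2)
  expected <- si * sj / n2
  (sij - expected) / ((si + sj) / 2 - expected)
}

# small empty-module spec helpers for generator configs
emptyModuleSpecs <- function() {
  data.frame(module = character(), nGenes = numeric(),
             strength = numeric(), traitTarget = numeric(),
             trait = character(), connGain = numeric())
}
emptyTermEnrichment <- function() {
  data.frame(module = character(), term = character(),
             fraction = numeric())
}

# compact generator config for tests
testConfig <- function(nGenes = 300, modules = NULL, seed = 1,
                       nTerms = 0, termEnrichment = NULL, ...) {
  simulationConfig(
    nGenes = nGenes,
    moduleSpecs = if (is.null(modules)) emptyModuleSpecs() else modules,
    nTerms = nTerms,
    termEnrichment = if (is.null(termEnrichment)) emptyTermEnrichment()
      else termEnrichment,
    seed = seed, ...)
}
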