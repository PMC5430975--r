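makeDataset <- function(cnt, lengths = NULL) {
  if (is.null(rownames(cnt))) rownames(cnt) <- sprintf("G%03d", seq_len(nrow(cnt)))
  if (is.null(colnames(cnt))) colnames(cnt) <- sprintf("S%02d", seq_len(ncol(cnt)))
  if (is.null(lengths)) lengths <- rep(1000, nrow(cnt))
  si <- data.frame(row.names = colnames(cnt),
                   treatment = rep_len(c("FBZ", "UNT"), ncol(cnt)),
                   breed = "D", sex = "F",
                   batch = rep_len(1:2, ncol(cnt)))
  CountDataset(cnt, lengths, si)
}

test_that("CPM follows its definition and handles edge cases", {
  cnt <- rbind(c(100, 0), c(0, 0), c(900e3, 50))
  cnt <- rbind(cnt, 1e6 - colSums(cnt))  # force library size 1e6
  ds <- makeDataset(cnt)
  cpm <- computeCPM(ds)
  expect_equal(unname(exprValues(cpm)[1, 1]), 100)   # unit library
  expect_equal(unname(exprValues(cpm)[2, ]), c(0, 0))  # all-zero gene
  # random matrix vs the one-line oracle
  set.seed(4)
  cnt2 <- matrix(rpois(300, 50), 50, 6)
  ds2 <- makeDataset(cnt2)
  f <- tmmFactors(ds2)
  got <- exprValues(computeCPM(ds2, f))
  want <- t(t(cnt2) / effectiveSizes(f)) * 1e6
  dimnames(want) <- dimnames(got)
  expect_equal(got, want, tolerance = 1e-12)
  # columns sum to 1e6 under unit factors
  expect_equal(unname(colSums(exprValues(computeCPM(ds2)))),
               rep(1e6, 6))
})

test_that("low-expression filter uses strict CPM > threshold in >= k samples", {
  v <- matrix(0, 3, 8, dimnames = list(c("keep", "dropEq", "dropFew"),
                                       sprintf("S%d", 1:8)))
  v["keep", 1:5] <- 2          # above 1 in exactly 5 samples -> kept
  v["dropEq", ] <- 1           # exactly 1 (not above) -> dropped
  v["dropFew", 1:4] <- 10      # above 1 in only 4 -> dropped
  cpm <- ExprMatrix(v, "CPM")
  expect_equal(filterLowExpression(cpm), "keep")
  expect_error(filterLowExpression(cpm, minSamples = 9), "exceeds")
  # random matrix vs brute-force row scan
  set.seed(11)
  r <- matrix(runif(600, 0, 3), 60, 10,
              dimnames = list(sprintf("G%03d", 1:60), sprintf("S%d", 1:10)))
  got <- filterLowExpression(ExprMatrix(r, "CPM"), minCPM = 1, minSamples = 5)
  want <- rownames(r)[apply(r, 1, function(x) sum(x > 1) >= 5)]
  expect_identical(got, want)
  # idempotent / order-independent
  perm <- sample(nrow(r))
  got2 <- filterLowExpression(ExprMatrix(r[perm, ], "CPM"))
  expect_setequal(got2, want)
})

test_that("TMM factors: identity, scale-invariance and oracle agreement", {
  set.seed(8)
  base <- rnbinom(400, mu = exp(rnorm(400, 4, 1)), size = 5) + 1
  cnt <- matrix(rep(base, 5), ncol = 5,
                dimnames = list(sprintf("G%03d", 1:400), sprintf("S%d", 1:5)))
  expect_equal(unname(normFactors(tmmFactors(cnt))), rep(1, 5))
  cnt2 <- cnt
  cnt2[, 3] <- cnt[, 3] * 2  # pure scaling absorbed by library size
  f2 <- normFactors(tmmFactors(cnt2))
  expect_equal(unname(f2), rep(1, 5), tolerance = 1e-10)
  # 10% of genes 4-fold up in one sample vs brute-force oracle
  for (i in 1:5) {
    set.seed(100 + i)
    m <- matrix(rnbinom(200 * 6, mu = exp(rnorm(200, 4, 1.2)), size = 8),
                200, 6, dimnames = list(sprintf("G%03d", 1:200),
                                        sprintf("S%d", 1:6)))
    up <- sample(200, 20)
    m[up, 4] <- m[up, 4] * 4
    expect_equal(unname(normFactors(tmmFactors(m))),
                 unname(tmmOracle(m)), tolerance = 1e-10)
  }
  expect_error(tmmFactors(cnt[, 1, drop = FALSE]), "2 samples")
})

test_that("RPKM follows its definition", {
  cnt <- matrix(10, 1, 2, dimnames = list("G1", c("A", "B")))
  cnt <- rbind(cnt, matrix(1e7 - 10, 1, 2, dimnames = list("G2", NULL)))
  ds <- makeDataset(cnt, lengths = c(1000, 500))
  rpkm <- computeRPKM(ds)
  expect_equal(unname(exprValues(rpkm)["G1", "A"]), 1)  # definitional
  ds2 <- makeDataset(cnt, lengths = c(2000, 500))
  expect_equal(unname(exprValues(computeRPKM(ds2))["G1", "A"]), 0.5)
  # random dataset vs formula oracle + RPKM/CPM ratio invariant
  set.seed(13)
  cnt3 <- matrix(rpois(200, 80), 40, 5,
                 dimnames = list(sprintf("G%03d", 1:40), sprintf("S%d", 1:5)))
  len <- round(runif(40, 200, 5000))
  ds3 <- makeDataset(cnt3, lengths = len)
  f <- tmmFactors(ds3)
  got <- exprValues(computeRPKM(ds3, f))
  want <- sweep(sweep(cnt3, 2, effectiveSizes(f), "/") * 1e9, 1, len, "/")
  expect_equal(got, want, tolerance = 1e-12)
  ratio <- got / exprValues(computeCPM(ds3, f))
  expect_equal(ratio, matrix(1e3 / len, 40, 5, dimnames = dimnames(got)),
               tolerance = 1e-12)
})

test_that("log2 transform maps 0/1/7 with prior 1 and rejects negatives", {
  v <- matrix(c(0, 1, 7, 3), 2, 2,
              dimnames = list(c("a", "b"), c("x", "y")))
  out <- exprValues(log2Transform(ExprMatrix(v, "RPKM")))
  expect_equal(unname(out), matrix(c(0, 1, 3, 2), 2, 2))
  expect_error(log2Transform(ExprMatrix(v - 5, "RPKM")), "nonnegative")
})

test_that("batch adjustment removes exact offsets and matches the OLS oracle", {
  set.seed(19)
  n <- 12
  batch <- rep(1:3, each = 4)
  base <- matrix(rnorm(20 * n, 8, 2), 20, n,
                 dimnames = list(sprintf("G%02d", 1:20), sprintf("S%02d", 1:n)))
  # single batch: identity
  e1 <- ExprMatrix(base, "log2RPKM")
  expect_equal(exprValues(batchAdjust(e1, rep(1, n))), base)
  # exact additive offsets, no noise: removed exactly
  off <- matrix(rnorm(20 * 3, 0, 1), 20, 3)
  shifted <- base + off[, batch]
  adj <- batchAdjust(ExprMatrix(shifted, "log2RPKM"), batch)
  for (g in 1:5) {
    ms <- tapply(exprValues(adj)[g, ], batch, mean)
    expect_equal(unname(diff(range(ms))), 0, tolerance = 1e-8)
  }
  # noisy case vs per-gene OLS projection with sum-to-zero batch coding
  noisy <- shifted + matrix(rnorm(20 * n, 0, 0.5), 20, n)
  got <- exprValues(batchAdjust(ExprMatrix(noisy, "log2RPKM"), batch))
  bf <- factor(batch)
  stats::contrasts(bf) <- stats::contr.sum(3)
  Xb <- stats::model.matrix(~bf)[, -1]
  want <- t(apply(noisy, 1, function(y) {
    fit <- stats::lm.fit(cbind(1, Xb), y)
    y - Xb %*% fit$coefficients[-1]
  }))
  dimnames(want) <- dimnames(got)
  expect_equal(got, want, tolerance = 1e-8)
  # idempotent
  again <- exprValues(batchAdjust(
    ExprMatrix(got, "batch_adjusted_log2RPKM"), batch))
  expect_equal(again, got, tolerance = 1e-8)
  # confounding detected
  trt <- as.numeric(batch == 1)
  expect_error(batchAdjust(ExprMatrix(noisy, "log2RPKM"),
                           batch = rep(1:2, c(4, 8)),
                           design = cbind(1, rep(c(1, 0), c(4, 8)))),
               "confounded")
})

test_that("classical MDS reproduces geometry and the spectral oracle", {
  set.seed(23)
  v <- matrix(rnorm(30 * 6, 5, 2), 30, 6,
              dimnames = list(sprintf("G%02d", 1:30), sprintf("S%d", 1:6)))
  v[, 6] <- v[, 5]  # duplicated sample
  e <- ExprMatrix(v, "log2CPM")
  out <- mdsTopSD(e, nTop = 30, nDims = 2)
  expect_equal(unlist(out[5, c("Dim1", "Dim2")]),
               unlist(out[6, c("Dim1", "Dim2")]), tolerance = 1e-10)
  # 3 equidistant samples form an equilateral triangle
  x <- matrix(0, 3, 3, dimnames = list(paste0("g", 1:3), paste0("s", 1:3)))
  x[1, 2] <- x[2, 3] <- x[3, 1] <- 1   # mutual distance sqrt(2)
  out3 <- mdsTopSD(ExprMatrix(x, "log2CPM"), nTop = 3, nDims = 2)
  pts <- as.matrix(out3[, c("Dim1", "Dim2")])
  dd <- as.matrix(dist(pts))
  expect_equal(unname(dd[upper.tri(dd)]), rep(sqrt(2), 3), tolerance = 1e-8)
  # spectral oracle: inter-point distances of the leading-eigenvalue
  # truncation
  top <- v[order(apply(v, 1, sd), decreasing = TRUE)[1:20], ]
  d <- dist(t(top))
  sp <- mdsSpectralOracle(d, 2)
  got <- mdsTopSD(e, nTop = 20, nDims = 2)
  expect_equal(unname(as.matrix(dist(as.matrix(got[, c("Dim1", "Dim2")])))),
               unname(as.matrix(dist(sp$points))), tolerance = 1e-8)
  expect_error(mdsTopSD(e, nTop = 31), "exceeds")
  expect_error(mdsTopSD(e, nTop = 10, nDims = 6), "exceeds")
})
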