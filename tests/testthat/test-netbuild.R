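blockExpr <- function(nPerBlock = c(30, 30), nBackground = 40, n = 30,
                      strength = 0.9, seed = 1) {
  set.seed(seed)
  nG <- sum(nPerBlock) + nBackground
  truth <- c(rep(paste0("B", seq_along(nPerBlock)), nPerBlock),
             rep("background", nBackground))
  v <- matrix(rnorm(nG * n), nG, n,
              dimnames = list(sprintf("G%03d", 1:nG), sprintf("S%02d", 1:n)))
  for (b in seq_along(nPerBlock)) {
    f <- rnorm(n)
    rows <- which(truth == paste0("B", b))
    v[rows, ] <- strength * outer(rep(1, length(rows)), f) +
      sqrt(1 - strength^2) * v[rows, ]
  }
  list(values = v, truth = setNames(truth, rownames(v)))
}

test_that("unsigned adjacency follows |cor|^beta", {
  x <- rbind(a = c(1, 2, 3, 4), b = c(4, 3, 2, 1))  # r = -1
  colnames(x) <- paste0("s", 1:4)
  a6 <- adjacencyMatrix(x, 6)
  expect_equal(unname(a6["a", "b"]), 1)  # |-1|^6
  # the signed variant suppresses anti-correlated pairs instead
  s6 <- adjacencyMatrix(x, 6, type = "signed")
  expect_equal(unname(s6["a", "b"]), 0)  # ((1-1)/2)^6
  y <- blockExpr(c(10), 20, n = 15, seed = 3)$values
  a1 <- adjacencyMatrix(y, 1)
  expect_equal(unname(a1), unname(abs(cor(t(y)))), tolerance = 1e-12)
  a18 <- adjacencyMatrix(y, 18)
  want <- abs(cor(t(y)))^18
  diag(want) <- 1
  expect_equal(a18, want, tolerance = 1e-12)
  expect_true(isSymmetric(a18))
  # constant genes dropped with a warning, or error in strict mode
  y2 <- rbind(y, const = rep(5, 15))
  expect_warning(ac <- adjacencyMatrix(y2, 6), "constant")
  expect_false("const" %in% rownames(ac))
  expect_error(adjacencyMatrix(y2, 6, strict = TRUE), "constant")
})

test_that("soft-threshold scan follows the scale-free selection rule", {
  # graded module loadings give an approximately scale-free degree
  # distribution, so the scan meets its fit target at some power
  set.seed(7)
  sizes <- c(150, 80, 40, 20)
  strengths <- c(0.95, 0.92, 0.9, 0.88)
  nG <- sum(sizes) + 210
  v <- matrix(rnorm(nG * 40), nG, 40,
              dimnames = list(sprintf("G%04d", 1:nG),
                              sprintf("S%02d", 1:40)))
  idx <- 1
  for (b in seq_along(sizes)) {
    f <- rnorm(40)
    rows <- idx:(idx + sizes[b] - 1)
    idx <- idx + sizes[b]
    lo <- runif(length(rows), 0.4, 1)
    v[rows, ] <- strengths[b] * outer(lo, f) +
      sqrt(1 - (strengths[b] * lo)^2) * v[rows, ]
  }
  ps <- pickSoftThreshold(v, powers = 1:20, targetR2 = 0.85)
  expect_true(any(ps$scan$r2_signed >= 0.85, na.rm = TRUE))
  ok <- which(!is.na(ps$scan$r2_signed) & ps$scan$r2_signed >= 0.85)
  expect_equal(ps$power, ps$scan$power[min(ok)])
  # mean connectivity nonincreasing in beta
  expect_true(all(diff(ps$scan$mean_k) <= 1e-8))
  # a tight block plus a majority of unconnected genes: many low-k genes,
  # few high-k genes, so the log-log slope is negative and the signed
  # index positive at any power
  v2 <- matrix(rnorm(300), 30, 10)
  v2[1:8, ] <- matrix(rep(rnorm(10), 8), 8, byrow = TRUE) +
    matrix(rnorm(80, 0, 1e-4), 8, 10)
  rownames(v2) <- sprintf("G%03d", 1:30); colnames(v2) <- sprintf("S%d", 1:10)
  psm <- pickSoftThreshold(v2, powers = c(2, 6))
  expect_true(all(psm$scan$r2_signed > 0, na.rm = TRUE))
})

test_that("TOM matches hand values and the triple-loop oracle", {
  ones <- matrix(1, 3, 3)
  expect_equal(tomSimilarity(ones), matrix(1, 3, 3))  # (1+1)/(2+1-1)
  eye <- diag(3)
  t0 <- tomSimilarity(eye)
  expect_equal(t0, diag(3))
  set.seed(17)
  for (i in 1:5) {
    a <- matrix(runif(400), 20, 20)
    a <- (a + t(a)) / 2
    diag(a) <- 1
    expect_equal(tomSimilarity(a), tomOracle(a), tolerance = 1e-12)
  }
  bad <- matrix(runif(16), 4, 4)
  expect_error(tomSimilarity(bad), "symmetric")
})

test_that("TOM stays within [0,1] on random adjacencies", {
  set.seed(19)
  for (i in 1:200) {
    n <- sample(4:12, 1)
    a <- matrix(runif(n * n), n, n)
    a <- (a + t(a)) / 2
    diag(a) <- 1
    tom <- tomSimilarity(a)
    expect_true(all(tom >= -1e-12 & tom <= 1 + 1e-12))
  }
})

test_that("average linkage reproduces hand UPGMA and the naive oracle", {
  d <- matrix(c(0, 0.1, 0.5,
                0.1, 0, 0.5,
                0.5, 0.5, 0), 3, 3,
              dimnames = list(letters[1:3], letters[1:3]))
  hc <- averageLinkage(d)
  expect_equal(hc$height, c(0.1, 0.5))
  set.seed(23)
  for (i in 1:5) {
    n <- sample(6:12, 1)
    m <- matrix(runif(n * n, 0.1, 1), n, n)
    m <- (m + t(m)) / 2
    diag(m) <- 0
    rownames(m) <- colnames(m) <- paste0("g", seq_len(n))
    expect_equal(sort(averageLinkage(m)$height), upgmaHeightsOracle(m),
                 tolerance = 1e-10)
  }
  # two well-separated blocks join each other last
  be <- blockExpr(c(10, 10), 0, n = 20, seed = 29)
  dt <- 1 - tomSimilarity(adjacencyMatrix(be$values, 10))
  hc2 <- averageLinkage(dt)
  top <- cutree(hc2, k = 2)
  expect_equal(as.integer(table(top)), c(10L, 10L))
  dna <- d; dna[1, 2] <- dna[2, 1] <- NA
  expect_error(averageLinkage(dna), "NA")
})

test_that("static tree cut recovers planted blocks and respects min size", {
  be <- blockExpr(c(50, 50), 100, n = 40, strength = 0.9, seed = 31)
  net <- buildNetwork(be$values, beta = 10, minModuleSize = 30)
  labels <- moduleLabels(net)
  mods <- setdiff(unique(labels), "grey")
  expect_equal(length(mods), 2)
  expect_gte(ari(labels, be$truth), 0.9)
  # modules are named by size rank from the fixed palette
  expect_true(all(mods %in% c("turquoise", "blue")))
  # min size above every cluster: everything grey
  netBig <- cutModules(net@dendrogram, minModuleSize = 90)
  expect_true(all(netBig == "grey"))
  # a 29-gene block stays grey at min size 30
  be2 <- blockExpr(c(29), 60, n = 40, strength = 0.9, seed = 37)
  net2 <- buildNetwork(be2$values, beta = 10, minModuleSize = 30)
  expect_true(all(moduleLabels(net2) == "grey"))
  expect_error(cutModules(net@dendrogram, cutHeight = 2), "cutHeight")
})

test_that("module labels are stable under gene reordering", {
  be <- blockExpr(c(40, 30), 50, n = 30, strength = 0.9, seed = 41)
  net1 <- buildNetwork(be$values, beta = 10)
  set.seed(43)
  perm <- sample(nrow(be$values))
  net2 <- buildNetwork(be$values[perm, ], beta = 10)
  l1 <- moduleLabels(net1)
  l2 <- moduleLabels(net2)[names(moduleLabels(net1))]
  expect_equal(l1, l2)
})

test_that("module recovery improves with planted strength", {
  ariAt <- function(strength, seed) {
    be <- blockExpr(c(40, 40), 60, n = 30, strength = strength,
                    seed = seed)
    net <- buildNetwork(be$values, beta = 10)
    ari(moduleLabels(net), be$truth)
  }
  means <- vapply(c(0.5, 0.7, 0.9), function(s)
    mean(vapply(1:5, function(sd) ariAt(s, 100 + sd), numeric(1))),
    numeric(1))
  expect_true(all(diff(means) >= -0.02))  # nondecreasing up to noise
  expect_gt(means[3], means[1])
})

test_that("eigengenes behave like first principal components", {
  be <- blockExpr(c(25), 0, n = 20, strength = 0.95, seed = 47)
  lab <- setNames(rep("blue", 25), rownames(be$values))
  me <- moduleEigengenes(be$values, lab)
  expect_equal(colnames(me$eigengenes), "blue")
  expect_equal(unname(sqrt(sum(me$eigengenes[, 1]^2))), 1,
               tolerance = 1e-10)
  # sign convention: positive correlation with the mean profile
  xs <- t(scale(t(be$values)))
  expect_gte(cor(me$eigengenes[, 1], colMeans(xs)), 0)
  # near-rank-1 module tracks the shared profile
  v <- outer(rep(1, 10), rnorm(20)) + matrix(rnorm(200, 0, 0.01), 10, 20)
  rownames(v) <- paste0("g", 1:10); colnames(v) <- paste0("s", 1:20)
  meV <- moduleEigengenes(v, setNames(rep("m", 10), rownames(v)))
  expect_gte(abs(cor(meV$eigengenes[, 1], v[1, ])), 0.99)
  expect_gte(meV$varExplained[["m"]], 0.95)
  # one-gene module: eigengene is the standardized gene, varExplained 1
  one <- moduleEigengenes(v[1, , drop = FALSE],
                          setNames("solo", "g1"))
  expect_equal(one$varExplained[["solo"]], 1)
  expect_equal(abs(cor(one$eigengenes[, 1], v[1, ])), 1, tolerance = 1e-10)
  # SVD oracle for variance explained
  sv <- svd(t(scale(t(be$values))))
  expect_equal(unname(me$varExplained["blue"]),
               sv$d[1]^2 / sum(sv$d^2), tolerance = 1e-10)
})

test_that("modules with correlated eigengenes merge at r > 0.85", {
  set.seed(53)
  n <- 30
  f <- rnorm(n)
  mk <- function(fvec, nGenes, noise) {
    outer(rep(1, nGenes), fvec) + matrix(rnorm(nGenes * n, 0, noise),
                                         nGenes, n)
  }
  v <- rbind(mk(f, 20, 0.35), mk(f, 15, 0.35), mk(rnorm(n), 18, 0.35))
  rownames(v) <- sprintf("G%02d", 1:53)
  colnames(v) <- sprintf("S%02d", 1:n)
  lab <- setNames(c(rep("blue", 20), rep("red", 15), rep("green", 18)),
                  rownames(v))
  me <- moduleEigengenes(v, lab)$eigengenes
  expect_gt(abs(cor(me[, "blue"], me[, "red"])), 0.85)
  merged <- mergeCloseModules(v, lab)
  expect_equal(length(unique(merged$labels)), 2)
  expect_equal(unique(merged$labels[1:35]), "blue")  # largest keeps its name
  # and a fixed point: remaining eigengenes below the merge threshold
  meF <- merged$eigengenes
  if (ncol(meF) > 1) {
    cc <- cor(meF)
    expect_true(all(abs(cc[upper.tri(cc)]) <= 0.85 + 1e-8))
  }
  # uncorrelated modules stay separate
  lab2 <- setNames(c(rep("blue", 35), rep("green", 18)), rownames(v))
  merged2 <- mergeCloseModules(v, lab2)
  expect_setequal(unique(merged2$labels), c("blue", "green"))
})
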