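# Acceptance-style experiments, shared between the acceptance tests and
# scripts/acceptance.R. Each function runs the package end to end on
# synthetic data and returns the measured quantities.

# --- criterion-style oracle sweeps -----------------------------------------

oracleSweep <- function(seed = 1, nInstances = 100) {
  set.seed(seed)
  dTom <- dTmm <- dUpgma <- dMds <- dKsD <- dKsP <- dHyp <- dBh <- 0
  for (i in seq_len(nInstances)) {
    # TOM
    n <- sample(5:15, 1)
    a <- matrix(runif(n * n), n, n); a <- (a + t(a)) / 2; diag(a) <- 1
    dTom <- max(dTom, max(abs(tomSimilarity(a) - tomOracle(a))))
    # TMM
    g <- sample(120:250, 1); s <- sample(4:6, 1)
    cnt <- matrix(rnbinom(g * s, mu = exp(rnorm(g, 4, 1.2)), size = 8),
                  g, s, dimnames = list(sprintf("G%03d", 1:g),
                                        sprintf("S%d", 1:s)))
    up <- sample(g, round(0.1 * g))
    cnt[up, sample(s, 1)] <- cnt[up, sample(s, 1)] * 4
    dTmm <- max(dTmm, max(abs(normFactors(tmmFactors(cnt)) -
                                tmmOracle(cnt))))
    # UPGMA merge heights
    m <- matrix(runif(64, 0.05, 1), 8, 8); m <- (m + t(m)) / 2; diag(m) <- 0
    dUpgma <- max(dUpgma, max(abs(sort(averageLinkage(m)$height) -
                                    upgmaHeightsOracle(m))))
    # classical MDS (compare inter-point distances)
    v <- matrix(rnorm(20 * 6, 5, 2), 20, 6,
                dimnames = list(sprintf("G%02d", 1:20),
                                sprintf("S%d", 1:6)))
    got <- mdsTopSD(ExprMatrix(v, "log2CPM"), nTop = 15, nDims = 2)
    top <- v[order(apply(v, 1, sd), decreasing = TRUE)[1:15], ]
    sp <- mdsSpectralOracle(dist(t(top)), 2)
    dMds <- max(dMds, max(abs(
      as.matrix(dist(as.matrix(got[, c("Dim1", "Dim2")]))) -
        as.matrix(dist(sp$points)))))
    # two-sample KS
    x <- rbeta(sample(10:60, 1), 2, 3); y <- rbeta(sample(10:60, 1), 3, 2)
    ks <- ksCompare(x, y); ko <- ksOracle(x, y)
    dKsD <- max(dKsD, abs(ks$D - ko$D))
    dKsP <- max(dKsP, abs(ks$pvalue - ko$p))
    # hypergeometric upper tail
    N <- sample(200:2000, 1); K <- sample(10:100, 1)
    nn <- sample(10:150, 1); x0 <- sample(0:min(K, nn), 1)
    dHyp <- max(dHyp, abs(
      phyper(x0 - 1, K, N - K, nn, lower.tail = FALSE) -
        hyperUpperOracle(x0, K, N, nn)))
    # BH step-up
    p <- runif(sample(5:50, 1))
    dBh <- max(dBh, max(abs(bhFDR(p) - bhOracle(p))))
  }
  list(tom = dTom, tmm = dTmm, upgma = dUpgma, mds = dMds,
       ks_d = dKsD, ks_p = dKsP, hypergeom = dHyp, bh = dBh,
       n = nInstances)
}

# --- DE calibration ---------------------------------------------------------

typeIExperiment <- function(seed = 1, nSims = 3, nGenes = 2000) {
  ps <- unlist(lapply(seq_len(nSims), function(i) {
    cfg <- simulationConfig(
      nGenes = nGenes, nTreated = 20, nUntreated = 20, nBatches = 5,
      moduleSpecs = emptyModuleSpecs(), deFraction = 0, nTerms = 0,
      termEnrichment = emptyTermEnrichment(), seed = seed * 1000 + i)
    sim <- simulateDataset(cfg)
    f <- tmmFactors(sim$dataset)
    kept <- filterLowExpression(computeCPM(sim$dataset, f))
    runDE(sim$dataset[kept, ], "FBZ", factors = f)$pvalue
  }))
  list(rate = mean(ps < 0.05), n = length(ps))
}

powerExperiment <- function(seed = 1, nGenes = 1000, nDe = 200) {
  set.seed(seed * 1000 + 77)
  n <- 40
  grp <- rep(c(1, 0), each = 20)
  batch <- factor(rep_len(1:5, n))
  phi <- rgamma(nGenes, 2, 20)
  mu <- matrix(100, nGenes, n)
  mu[seq_len(nDe), grp == 1] <- 100 * 4       # planted log2FC = 2
  bl <- matrix(rnorm(nGenes * 5, sd = 0.1), nGenes, 5)
  mu <- mu * exp(bl[, as.integer(batch)])
  cnt <- matrix(rnbinom(nGenes * n, mu = mu, size = rep(1 / phi, n)),
                nGenes, n, dimnames = list(sprintf("G%04d", 1:nGenes),
                                           sprintf("S%02d", 1:n)))
  X <- cbind(Intercept = 1, treated = grp,
             stats::model.matrix(~batch)[, -1])
  fac <- tmmFactors(cnt)
  disp <- estimateDispersionsMoM(cnt, X, fac)
  fit <- fitNbGlm(cnt, X, fac, disp)
  res <- lrtContrast(fit, cnt, stats::setNames(1, "treated"))
  list(power = mean(res$fdr[seq_len(nDe)] < 0.05), n = nDe)
}

# --- module recovery --------------------------------------------------------

# Planted blocks span half the desk-scale gene universe, which breaks the
# majority-unchanged assumption behind between-sample normalization; the
# clustering experiments therefore run on unnormalized log counts.
recoveryOnce <- function(seed, beta = 10) {
  cfg <- simulationConfig(
    nGenes = 200, nTreated = 20, nUntreated = 20, nBatches = 5,
    moduleSpecs = data.frame(
      module = c("M1", "M2"), nGenes = c(50, 50), strength = 0.9,
      traitTarget = 0, trait = c("CL", "AUC"), connGain = 0),
    deFraction = 0, nTerms = 0,
    termEnrichment = emptyTermEnrichment(), seed = seed)
  sim <- simulateDataset(cfg)
  lc <- log2(counts(sim$dataset) + 1)
  net <- buildNetwork(lc, beta = beta)
  lab <- moduleLabels(net)
  c(mods = length(setdiff(unique(lab), "grey")),
    ari = ari(lab, moduleAssignment(sim$truth)))
}

recoveryExperiment <- function(seed = 1, nSeeds = 25) {
  res <- vapply(seq_len(nSeeds), function(i)
    recoveryOnce(seed * 1000 + i), numeric(2))
  list(rate = mean(res["mods", ] == 2 & res["ari", ] >= 0.9),
       meanAri = mean(res["ari", ]), n = nSeeds)
}

# --- selection recovery -----------------------------------------------------

selectionOnce <- function(seed) {
  cfg <- simulationConfig(
    nGenes = 420, nTreated = 20, nUntreated = 20, nBatches = 5,
    moduleSpecs = data.frame(
      module = c("M1", "M2", "M3", "M4"),
      nGenes = c(80, 60, 60, 60), strength = 0.8,
      traitTarget = c(0.5, 0, 0, 0),
      trait = c("CL", "AUC", "MRT", "T12"),
      connGain = 0,
      deFraction = c(0.2, 0, 0, 0)),
    deLog2FC = 2, nTerms = 0,
    termEnrichment = emptyTermEnrichment(), seed = seed)
  sim <- simulateDataset(cfg)
  lab <- moduleAssignment(sim$truth)
  modLab <- lab[lab != "background"]
  f <- tmmFactors(sim$dataset)
  kept <- filterLowExpression(computeCPM(sim$dataset, f))
  de <- runDE(sim$dataset[kept, ], "FBZ", factors = f)
  si <- sampleInfo(sim$dataset)
  trt <- si$treatment != "UNT"
  # eigengenes on unnormalized log counts: at desk scale the planted
  # modules dominate the library, so per-sample normalization would mix
  # the module factors into every profile
  lc <- log2(counts(sim$dataset)[kept, ] + 1)
  me <- moduleEigengenes(lc[, trt],
                         modLab[names(modLab) %in% kept])$eigengenes
  mt <- moduleTraitCorrelations(me, pkTraits(sim$dataset)[trt, ])
  sel <- selectModules(mt, de, modLab[names(modLab) %in% kept])
  selected <- sel$module[sel$selected]
  identical(selected, "M1")
}

selectionExperiment <- function(seed = 1, nSeeds = 100) {
  hits <- vapply(seq_len(nSeeds), function(i)
    selectionOnce(seed * 1000 + i), logical(1))
  list(rate = mean(hits), n = nSeeds)
}

# --- differential connectivity ----------------------------------------------

diffconnOnce <- function(seed, beta = 10, gain = 1, size = 160) {
  cfg <- simulationConfig(
    nGenes = size + 40, nTreated = 20, nUntreated = 20, nBatches = 5,
    moduleSpecs = data.frame(
      module = "M1", nGenes = size, strength = 0.8, traitTarget = 0,
      trait = "CL", connGain = gain),
    deFraction = 0, nTerms = 0,
    termEnrichment = emptyTermEnrichment(), seed = seed)
  sim <- simulateDataset(cfg)
  lc <- log2(counts(sim$dataset) + 1)
  trt <- sampleInfo(sim$dataset)$treatment != "UNT"
  genes <- names(moduleAssignment(sim$truth))[
    moduleAssignment(sim$truth) == "M1"]
  kT <- scaledConnectivity(lc[, trt], genes, beta)
  kU <- scaledConnectivity(lc[, !trt], genes, beta)
  ks <- ksCompare(kT, kU)
  sw <- ksCompare(kU, kT)
  c(meanDk = mean(kT - kU), p = ks$pvalue,
    antisym = as.numeric(max(abs((kT - kU) + (kU - kT))) == 0 &&
                           ks$D == sw$D))
}

diffconnExperiment <- function(seed = 1, nSeeds = 100) {
  res <- vapply(seq_len(nSeeds), function(i)
    diffconnOnce(seed * 1000 + i), numeric(3))
  list(rate = mean(res["meanDk", ] > 0 & res["p", ] < 0.001),
       meanDk = mean(res["meanDk", ]),
       antisym = all(res["antisym", ] == 1), n = nSeeds)
}

# --- determinism and round trips --------------------------------------------

determinismExperiment <- function(seed = 1, dir = tempfile()) {
  cfg <- simulationConfig(
    nGenes = 300, nTreated = 20, nUntreated = 20,
    moduleSpecs = data.frame(
      module = c("M1", "M2"), nGenes = c(60, 40), strength = 0.9,
      traitTarget = c(0.6, 0), trait = c("CL", "AUC"),
      connGain = c(0.5, 0), deFraction = c(0.25, 0)),
    deLog2FC = 2, nTerms = 30,
    termEnrichment = data.frame(module = "M1", term = "TERM001",
                                fraction = 0.4),
    seed = seed)
  d1 <- file.path(dir, "a"); d2 <- file.path(dir, "b")
  sim1 <- simulateDataset(cfg)
  sim2 <- simulateDataset(cfg)
  writeDataset(sim1$dataset, file.path(d1, "in"), truth = sim1$truth)
  writeDataset(sim2$dataset, file.path(d2, "in"), truth = sim2$truth)
  runArm(runConfig(arm = "FBZ", outputDir = file.path(d1, "out"),
                   seed = seed), dataset = sim1$dataset)
  runArm(runConfig(arm = "FBZ", outputDir = file.path(d2, "out"),
                   seed = seed), dataset = sim2$dataset)
  sameBytes <- function(f1, f2)
    identical(readBin(f1, "raw", file.size(f1)),
              readBin(f2, "raw", file.size(f2)))
  simFiles <- list.files(file.path(d1, "in"))
  # summary.json carries wall time and config.yaml the output path; the
  # analysis outputs themselves must be byte-identical
  outFiles <- setdiff(list.files(file.path(d1, "out")),
                      c("summary.json", "config.yaml"))
  det <- all(vapply(simFiles, function(f)
    sameBytes(file.path(d1, "in", f), file.path(d2, "in", f)),
    logical(1))) &&
    all(vapply(outFiles, function(f)
      sameBytes(file.path(d1, "out", f), file.path(d2, "out", f)),
      logical(1)))
  ds2 <- readDataset(file.path(d1, "in"))
  tr2 <- readGroundTruth(file.path(d1, "in", "truth.json"))
  rt <- identical(counts(ds2), counts(sim1$dataset)) &&
    isTRUE(all.equal(pkTraits(ds2), pkTraits(sim1$dataset))) &&
    isTRUE(all.equal(moduleAssignment(tr2),
                     moduleAssignment(sim1$truth))) &&
    isTRUE(all.equal(latentFactors(tr2), latentFactors(sim1$truth)))
  list(deterministic = det, roundtrip = rt)
}
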