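#' Configure the synthetic liver RNA-seq generator
#'
#' Builds a [SimulationConfig-class] describing one drug arm: treated and
#' untreated animals, batches, planted co-expression modules whose latent
#' factors track pharmacokinetic (PK) parameters, treatment-DE genes inside
#' the modules, multiplicative batch effects, and term annotations enriched
#' in chosen modules. The defaults emulate the study design the package
#' models: ~12,000 genes in 20 treated plus 20 untreated animals spread over
#' 5 batches, with planted modules sized and trait-correlated like the
#' module/PK associations the method is designed to detect.
#'
#' @param nGenes total number of genes.
#' @param nTreated,nUntreated samples per group.
#' @param nBatches number of batches; samples are assigned cyclically so
#'   batches span both groups.
#' @param moduleSpecs data.frame with columns `module`, `nGenes`, `strength`
#'   (latent factor strength in \[0,1\]), `traitTarget` (target eigengene-trait
#'   Pearson correlation), `trait` (PK parameter name), `connGain`
#'   (connectivity gain in treated samples, >= 0: the factor loading in
#'   treated samples is multiplied by `1 + connGain`).
#' @param deFraction fraction of each module's genes given a true treatment
#'   effect; an optional `deFraction` column in `moduleSpecs` overrides it
#'   per module.
#' @param deLog2FC log2 fold change added to treated means of DE genes.
#' @param dispShape,dispRate gamma distribution of gene-wise NB dispersions.
#' @param batchSD SD of the per-(gene,batch) natural-log multiplier.
#' @param lengthRange bp interval gene lengths are drawn from.
#' @param nTerms number of annotation terms.
#' @param termEnrichment data.frame `module`, `term`, `fraction`: that
#'   fraction of the module's genes is added to the term's gene set.
#' @param treatment treated-arm label (`"FBZ"` or `"FLU"`).
#' @param seed integer RNG seed; identical seeds give byte-identical output.
#' @return A validated [SimulationConfig-class].
#' @export
simulationConfig <- function(nGenes = 12000,
                             nTreated = 20,
                             nUntreated = 20,
                             nBatches = 5,
                             moduleSpecs = data.frame(
                               module = c("M1", "M2", "M3", "M4"),
                               nGenes = c(620, 180, 120, 80),
                               strength = 0.8,
                               traitTarget = c(-0.44, 0.50, -0.42, -0.38),
                               trait = c("CL", "TMAX", "CL", "MRT"),
                               connGain = 0.5),
                             deFraction = 0.15,
                             deLog2FC = 1,
                             dispShape = 2,
                             dispRate = 20,
                             batchSD = 0.1,
                             lengthRange = c(300, 10000),
                             nTerms = 200,
                             termEnrichment = data.frame(
                               module = c("M1", "M2", "M3", "M4"),
                               term = c("TERM001", "TERM002", "TERM003",
                                        "TERM004"),
                               fraction = 0.2),
                             treatment = "FBZ",
                             seed = 1) {
  new("SimulationConfig",
      nGenes = nGenes, nTreated = nTreated, nUntreated = nUntreated,
      nBatches = nBatches, moduleSpecs = moduleSpecs,
      deFraction = deFraction, deLog2FC = deLog2FC,
      dispShape = dispShape, dispRate = dispRate, batchSD = batchSD,
      lengthRange = lengthRange, nTerms = nTerms,
      termEnrichment = termEnrichment, treatment = treatment, seed = seed)
}

# realistic location/scale used to place standardized PK traits on their
# natural units (h, h*ug/mL, L/h/kg, ...)
pkTraitScales <- function() {
  data.frame(
    trait = pkTraitNames(),
    mean = c(10, 50, 0.25, 15, 2, 5, 2),
    sd = c(3, 15, 0.08, 4, 0.5, 1.5, 0.6))
}

#' Generate a synthetic count dataset with planted structure
#'
#' Draws negative-binomial counts on top of log-scale gene means. Genes of a
#' planted module share a per-sample latent factor scaled by the module's
#' strength; in treated samples the factor loading is multiplied by
#' `1 + connGain`, raising within-module co-expression (and hence network
#' connectivity) in the treated group. A per-module fraction of genes gets
#' `deLog2FC` added to treated means. Per-(gene,batch) log-normal multipliers
#' create removable batch effects. Each PK trait assigned to a module is a
#' noisy linear function of that module's latent factor over treated samples,
#' tuned to the target correlation; traits exist only for treated animals.
#' Background genes carry independent noise only.
#'
#' @param config a [SimulationConfig-class].
#' @return list with elements `dataset` (a [CountDataset-class]) and
#'   `truth` (a [GroundTruth-class]).
#' @export
simulateDataset <- function(config) {
  stopifnot(is(config, "SimulationConfig"))
  validObject(config)
  withSeed(config@seed, {
    nG <- config@nGenes
    nT <- config@nTreated
    nU <- config@nUntreated
    nS <- nT + nU
    genes <- sprintf("G%05d", seq_len(nG))
    samples <- c(sprintf("%s%02d", config@treatment, seq_len(nT)),
                 sprintf("UNT%02d", seq_len(nU)))
    treated <- c(rep(TRUE, nT), rep(FALSE, nU))

    sampleInfo <- data.frame(
      row.names = samples,
      treatment = ifelse(treated, config@treatment, "UNT"),
      breed = rep_len(c("D", "H", "L", "Y"), nS),
      sex = rep_len(c("F", "CM"), nS),
      batch = rep_len(seq_len(config@nBatches), nS))

    ms <- config@moduleSpecs
    assign <- rep("background", nG)
    if (nrow(ms)) {
      idx <- 1L
      for (m in seq_len(nrow(ms))) {
        take <- seq.int(idx, idx + ms$nGenes[m] - 1L)
        assign[take] <- ms$module[m]
        idx <- idx + ms$nGenes[m]
      }
    }
    names(assign) <- genes

    baseLog <- stats::rnorm(nG, mean = log(150), sd = 1.5)
    phi <- pmax(stats::rgamma(nG, shape = config@dispShape,
                              rate = config@dispRate), 1e-8)
    loading <- stats::runif(nG, 0.8, 1.2)

    nMod <- nrow(ms)
    fac <- matrix(0, nrow = max(nMod, 0), ncol = nS,
                  dimnames = list(ms$module, samples))
    if (nMod) fac[] <- stats::rnorm(nMod * nS)

    logMu <- matrix(baseLog, nrow = nG, ncol = nS,
                    dimnames = list(genes, samples))
    gainMult <- function(g) ifelse(treated, 1 + g, 1)
    for (m in seq_len(nMod)) {
      rows <- which(assign == ms$module[m])
      eff <- outer(ms$strength[m] * loading[rows],
                   fac[m, ] * gainMult(ms$connGain[m]))
      logMu[rows, ] <- logMu[rows, ] + eff
    }

    de <- character(0)
    if (nMod) {
      deFrac <- if ("deFraction" %in% colnames(ms)) ms$deFraction else
        rep(config@deFraction, nMod)
      for (m in seq_len(nMod)) {
        rows <- which(assign == ms$module[m])
        k <- round(deFrac[m] * length(rows))
        if (k > 0) {
          pick <- sample(rows, k)
          logMu[pick, treated] <- logMu[pick, treated] +
            config@deLog2FC * log(2)
          de <- c(de, genes[pick])
        }
      }
    }

    batchLog <- matrix(0, nG, config@nBatches)
    if (config@batchSD > 0)
      batchLog[] <- stats::rnorm(nG * config@nBatches, sd = config@batchSD)
    logMu <- logMu + batchLog[, sampleInfo$batch, drop = FALSE]

    mu <- exp(logMu)
    cnt <- matrix(stats::rnbinom(nG * nS, mu = mu,
                                 size = rep(1 / phi, nS)),
                  nrow = nG, dimnames = dimnames(mu))

    lengths <- round(stats::runif(nG, config@lengthRange[1],
                                  config@lengthRange[2]))
    names(lengths) <- genes

    # PK traits: noisy linear readouts of the assigned module's factor over
    # treated samples, then placed on natural PK units.
    scales <- pkTraitScales()
    traits <- as.data.frame(matrix(stats::rnorm(nT * 7), nT, 7,
                                   dimnames = list(samples[treated],
                                                   pkTraitNames())))
    for (m in seq_len(nMod)) {
      tn <- ms$trait[m]
      r <- ms$traitTarget[m]
      if (!tn %in% pkTraitNames() || r == 0) next
      z <- fac[m, treated]
      traits[[tn]] <- r * z + sqrt(1 - r^2) * stats::rnorm(nT)
    }
    for (tn in pkTraitNames()) {
      sc <- scales[scales$trait == tn, ]
      traits[[tn]] <- sc$mean + sc$sd * traits[[tn]]
    }

    annotation <- NULL
    if (config@nTerms > 0) {
      termIds <- sprintf("TERM%03d", seq_len(config@nTerms))
      maxSize <- min(80, max(2, floor(nG / 2)))
      sets <- lapply(termIds, function(t)
        sample(genes, sample(seq(min(20, maxSize), maxSize), 1)))
      names(sets) <- termIds
      te <- config@termEnrichment
      for (i in seq_len(nrow(te))) {
        rows <- genes[assign == te$module[i]]
        if (!length(rows) || !te$term[i] %in% termIds) next
        k <- round(te$fraction[i] * length(rows))
        if (k > 0)
          sets[[te$term[i]]] <- union(sets[[te$term[i]]], sample(rows, k))
      }
      annotation <- data.frame(
        gene_id = unlist(sets, use.names = FALSE),
        term_id = rep(names(sets), lengths(sets)))
      annotation$term_name <- paste("process",
                                    sub("TERM0*", "", annotation$term_id))
      annotation <- annotation[order(annotation$term_id,
                                     annotation$gene_id), ]
      rownames(annotation) <- NULL
    }

    dataset <- CountDataset(cnt, lengths, sampleInfo,
                            traits = traits, annotation = annotation)
    truth <- new("GroundTruth",
                 moduleAssignment = assign,
                 deGenes = sort(de),
                 traitLoadings = data.frame(
                   module = ms$module, trait = ms$trait,
                   target = ms$traitTarget,
                   connGain = ms$connGain,
                   stringsAsFactors = FALSE),
                 latentFactors = fac,
                 batchSummary = data.frame(
                   sample_id = samples,
                   batch = sampleInfo$batch,
                   mean_log_multiplier =
                     colMeans(batchLog)[sampleInfo$batch],
                   stringsAsFactors = FALSE))
    list(dataset = dataset, truth = truth)
  })
}
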