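#' Resolved run configuration
#'
#' Collects every stage parameter of the per-arm analysis with defaults
#' equal to the published settings this pipeline models: CPM filter
#' (> 1 in >= 5 samples), soft power chosen by the scale-free criterion
#' (target signed R^2 0.90), minimum module size 30, eigengene merge height
#' 0.15, module selection |r| > 0.30 & p < 0.10 & DE fraction >= 0.10
#' (FDR < 0.05), hub threshold 0.6.
#'
#' @param input directory of TSV inputs (see [readDataset()]), or `NULL`
#'   when a dataset object is passed to [runArm()] directly.
#' @param arm treated arm, "FBZ" or "FLU".
#' @param outputDir directory for intermediates and the run summary.
#' @param minCPM,minSamples expression filter.
#' @param beta soft power; defaults to the published 18, `NULL` selects it
#'   by the scale-free scan (`powers`, `targetR2`).
#' @param minModuleSize,mergeCutHeight module detection/merging.
#' @param rMin,pMax,deFracMin,fdrMax module selection filters.
#' @param hubThreshold,hubOn differential connectivity.
#' @param shrinkWeight dispersion shrinkage weight.
#' @param logPrior prior count for log2 transforms.
#' @param seed RNG seed recorded with the run.
#' @return list of class `coexPKConfig`.
#' @export
runConfig <- function(input = NULL, arm = "FBZ", outputDir = NULL,
                      minCPM = 1, minSamples = 5,
                      beta = 18, powers = 1:20, targetR2 = 0.90,
                      minModuleSize = 30, mergeCutHeight = 0.15,
                      rMin = 0.30, pMax = 0.10, deFracMin = 0.10,
                      fdrMax = 0.05, hubThreshold = 0.6, hubOn = "delta",
                      shrinkWeight = 0.7, logPrior = 1, seed = 1) {
  cfg <- as.list(environment())
  class(cfg) <- "coexPKConfig"
  cfg
}

writeTsv <- function(df, dir, file) {
  utils::write.table(df, file.path(dir, file), sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' Run the full per-arm analysis
#'
#' Executes, in order: CPM filtering across all samples, TMM normalization,
#' negative-binomial differential expression (treated vs untreated within
#' the arm), RPKM + log2 + batch adjustment, unsigned network construction
#' and module detection on the treated samples, module-trait correlation
#' and the three-filter selection, per-condition scaled connectivity with
#' hub calling and KS comparison for the selected modules, and term
#' enrichment of the selected modules against the expressed background.
#' Every intermediate is written as TSV beside a machine-readable
#' `summary.json` and the resolved `config.yaml`.
#'
#' @param config a `coexPKConfig` from [runConfig()].
#' @param dataset optional [CountDataset-class]; when `NULL` the bundle is
#'   read from `config$input`.
#' @return the run summary, invisibly (a nested list, also serialized to
#'   `summary.json` when `config$outputDir` is set).
#' @export
runArm <- function(config, dataset = NULL) {
  stopifnot(inherits(config, "coexPKConfig"))
  t0 <- proc.time()[["elapsed"]]
  if (is.null(dataset)) {
    if (is.null(config$input)) stop("config$input or a dataset is required")
    dataset <- readDataset(config$input)
  }
  arm <- config$arm
  si <- sampleInfo(dataset)
  if (!any(si$treatment == arm))
    stop(sprintf("no treated samples for arm %s", arm))
  if (!any(si$treatment == "UNT"))
    stop("no untreated (UNT) samples")
  outDir <- config$outputDir
  if (!is.null(outDir) && !dir.exists(outDir))
    dir.create(outDir, recursive = TRUE)
  summ <- list(arm = arm, seed = config$seed, stages = list())
  stage <- function(name, value) summ$stages[[name]] <<- value

  # --- filter + normalize (all samples jointly) ---
  factors <- tmmFactors(dataset)
  cpm <- computeCPM(dataset, factors)
  keptGenes <- filterLowExpression(cpm, config$minCPM, config$minSamples)
  ds <- dataset[keptGenes, ]
  stage("filter", list(genes_in = nrow(dataset), genes_kept =
                         length(keptGenes), min_cpm = config$minCPM,
                       min_samples = config$minSamples))

  # --- differential expression within the arm ---
  de <- runDE(ds, arm, factors = factors,
              shrinkWeight = config$shrinkWeight)
  stage("de", list(n_genes = nrow(de),
                   n_fdr05 = sum(de$fdr < config$fdrMax)))

  # --- expression matrix for the network ---
  rpkm <- computeRPKM(ds, factors)
  lrpkm <- log2Transform(rpkm, prior = config$logPrior)
  inArm <- si$treatment %in% c(arm, "UNT")
  vArm <- exprValues(lrpkm)[, inArm, drop = FALSE]
  siArm <- si[inArm, , drop = FALSE]
  exprArm <- ExprMatrix(vArm, exprScale(lrpkm), provenance(lrpkm))
  design <- stats::model.matrix(~treatment, data = siArm)
  adj <- batchAdjust(exprArm, siArm$batch, design = design)
  treatedIdx <- siArm$treatment == arm
  vAdj <- exprValues(adj)
  exprTreated <- vAdj[, treatedIdx, drop = FALSE]
  exprUntreated <- vAdj[, !treatedIdx, drop = FALSE]

  cpmArm <- ExprMatrix(exprValues(computeCPM(ds, factors))[, inArm,
                                                           drop = FALSE],
                       "CPM", "CPM")
  mds <- mdsTopSD(log2Transform(cpmArm, prior = config$logPrior),
                  nTop = min(500, length(keptGenes)), nDims = 2)

  # --- network on the treated samples ---
  net <- buildNetwork(exprTreated, beta = config$beta,
                      powers = config$powers, targetR2 = config$targetR2,
                      minModuleSize = config$minModuleSize,
                      mergeCutHeight = config$mergeCutHeight)
  labels <- moduleLabels(net)
  nMod <- length(setdiff(unique(labels), "grey"))
  stage("network", list(beta = softPower(net), modules = nMod,
                        grey = sum(labels == "grey")))

  # --- module-trait integration ---
  traits <- pkTraits(ds)
  mt <- moduleTraitCorrelations(eigengenes(net), traits)
  sel <- selectModules(mt, de, labels, rMin = config$rMin,
                       pMax = config$pMax, deFracMin = config$deFracMin,
                       fdrMax = config$fdrMax)
  selected <- sel$module[sel$selected]
  stage("selection", list(modules_tested = nrow(sel),
                          modules_selected = length(selected),
                          selected = as.list(selected)))
  kmeObj <- moduleMembership(exprTreated, eigengenes(net))

  # --- differential connectivity on the selected modules ---
  dcc <- NULL
  if (length(selected)) {
    dcc <- moduleDifferentialConnectivity(
      exprTreated, exprUntreated, labels, modules = selected,
      beta = softPower(net), hubThreshold = config$hubThreshold,
      hubOn = config$hubOn)
    stage("connectivity", list(
      modules = length(selected), hubs = sum(dcc$connectivity$hub),
      ks_min_p = min(dcc$ks$pvalue),
      mean_delta_k = mean(dcc$connectivity$delta_k)))
  } else stage("connectivity", list(modules = 0))

  # --- enrichment of the selected modules ---
  enr <- NULL
  ann <- geneAnnotation(dataset)
  if (!is.null(ann) && length(selected)) {
    enr <- moduleEnrichment(labels, ann, keptGenes, modules = selected)
    stage("enrichment", list(
      tests = nrow(enr), significant = sum(enr$fdr < config$fdrMax),
      top_terms = as.list(vapply(selected, function(m) {
        sub <- enr[enr$module == m, ]
        sub$term_id[which.min(sub$pvalue)]
      }, character(1)))))
  } else stage("enrichment", list(tests = 0))

  summ$wall_time_s <- proc.time()[["elapsed"]] - t0

  if (!is.null(outDir)) {
    writeTsv(de, outDir, "de_results.tsv")
    writeTsv(data.frame(gene_id = names(labels), module_label = labels),
             outDir, "modules.tsv")
    me <- eigengenes(net)  # stored samples x modules; emitted module x sample
    writeTsv(data.frame(module = colnames(me), t(me), check.names = FALSE),
             outDir, "eigengenes.tsv")
    if (nrow(net@scan))
      writeTsv(net@scan[, c("power", "r2_signed", "mean_k", "median_k")],
               outDir, "soft_threshold_scan.tsv")
    writeTsv(mds, outDir, "mds.tsv")
    writeTsv(mt, outDir, "module_trait.tsv")
    writeTsv(sel, outDir, "module_selection.tsv")
    kmeDf <- data.frame(gene_id = rownames(kmeObj$kme), kmeObj$kme,
                        check.names = FALSE)
    writeTsv(kmeDf, outDir, "module_membership.tsv")
    if (!is.null(dcc)) {
      writeTsv(dcc$connectivity, outDir, "connectivity.tsv")
      writeTsv(dcc$ks, outDir, "ks_tests.tsv")
    }
    if (!is.null(enr)) writeTsv(enr, outDir, "enrichment.tsv")
    cfgOut <- config
    class(cfgOut) <- NULL
    cfgOut$powers <- paste(range(config$powers), collapse = ":")
    yaml::write_yaml(cfgOut, file.path(outDir, "config.yaml"))
    jsonlite::write_json(summ, file.path(outDir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(summ)
}

cliUsage <- function() {
  paste(
    "usage: coexpk <subcommand> [options]",
    "  simulate  --out DIR [--seed N] [--config YAML]",
    "  run-all   --config YAML [--out DIR] [--seed N]",
    "options are '--flag value' pairs; --config YAML keys override",
    "runConfig()/simulationConfig() defaults.", sep = "\n")
}

parseCliArgs <- function(argv) {
  out <- list()
  i <- 1
  while (i <= length(argv)) {
    a <- argv[i]
    if (!startsWith(a, "--"))
      stop(sprintf("unexpected argument '%s'", a))
    if (i == length(argv)) stop(sprintf("flag %s lacks a value", a))
    out[[substring(a, 3)]] <- argv[i + 1]
    i <- i + 2
  }
  out
}

#' Command-line entry point
#'
#' A thin shell over the package functions, suitable for
#' `Rscript -e 'coexPK::pipelineCLI(commandArgs(TRUE))'`. Subcommand
#' `simulate` writes a synthetic dataset bundle; `run-all` executes
#' [runArm()] on a config file. Per-stage work is exposed through the
#' exported functions themselves.
#'
#' @param argv character vector of arguments (subcommand first).
#' @return integer exit status (0 success, 1 runtime error, 2 usage error),
#'   invisibly.
#' @export
pipelineCLI <- function(argv = commandArgs(trailingOnly = TRUE)) {
  fail <- function(status, msg) {
    message(msg)
    invisible(status)
  }
  if (!length(argv)) return(fail(2L, cliUsage()))
  sub <- argv[1]
  if (!sub %in% c("simulate", "run-all")) {
    return(fail(2L, paste0("unknown subcommand '", sub, "'\n", cliUsage())))
  }
  opts <- tryCatch(parseCliArgs(argv[-1]), error = function(e) e)
  if (inherits(opts, "error"))
    return(fail(2L, paste0(conditionMessage(opts), "\n", cliUsage())))
  res <- tryCatch({
    cfgFile <- opts$config
    over <- if (!is.null(cfgFile)) yaml::read_yaml(cfgFile) else list()
    if (sub == "simulate") {
      if (is.null(opts$out)) stop("simulate requires --out")
      args <- over[intersect(names(over),
                             names(formals(simulationConfig)))]
      for (tab in c("moduleSpecs", "termEnrichment"))
        if (!is.null(args[[tab]]) && !is.data.frame(args[[tab]]))
          args[[tab]] <- if (length(args[[tab]]))
            do.call(rbind, lapply(args[[tab]], as.data.frame)) else
            data.frame()
      if (!is.null(opts$seed)) args$seed <- as.integer(opts$seed)
      sim <- simulateDataset(do.call(simulationConfig, args))
      writeDataset(sim$dataset, opts$out, truth = sim$truth)
    } else {
      args <- over[intersect(names(over), names(formals(runConfig)))]
      if (!is.null(opts$out)) args$outputDir <- opts$out
      if (!is.null(opts$seed)) args$seed <- as.integer(opts$seed)
      cfg <- do.call(runConfig, args)
      if (is.null(cfg$input)) stop("config must name the input directory")
      if (!file.exists(file.path(cfg$input, "counts.tsv")))
        stop(sprintf("missing counts file: %s",
                     file.path(cfg$input, "counts.tsv")))
      runArm(cfg)
    }
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(res)
}
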