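#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay rowData colData
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

pkTraitNames <- function() c("T12", "AUC", "CL", "MRT", "VDSS", "CMAX", "TMAX")

validScales <- function() {
  c("CPM", "log2CPM", "RPKM", "log2RPKM", "batch_adjusted_log2RPKM",
    "batch_adjusted_log2CPM")
}

#' Count dataset bundle
#'
#' `CountDataset` wraps a [SummarizedExperiment::SummarizedExperiment] holding
#' the gene-level count matrix (assay `"counts"`), per-gene lengths in bp
#' (`rowData$length_bp`), per-sample metadata (`treatment`, `breed`, `sex`,
#' `batch` in `colData`) and the pharmacokinetic trait table (trait columns in
#' `colData`; `NA` for samples without PK estimates, typically the untreated
#' arm).
#'
#' @slot .
#' @name CountDataset-class
#' @exportClass CountDataset
setClass("CountDataset", contains = "SummarizedExperiment")

setValidity("CountDataset", function(object) {
  msg <- character()
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'counts' is required")
  else {
    m <- SummarizedExperiment::assay(object, "counts")
    if (any(m < 0)) msg <- c(msg, "counts must be nonnegative")
    if (any(abs(m - round(m)) > 1e-8)) msg <- c(msg, "counts must be integers")
  }
  if (!"length_bp" %in% colnames(rowData(object)))
    msg <- c(msg, "rowData column 'length_bp' is required")
  else if (any(rowData(object)$length_bp <= 0))
    msg <- c(msg, "gene lengths must be positive")
  need <- c("treatment", "breed", "sex", "batch")
  miss <- setdiff(need, colnames(colData(object)))
  if (length(miss))
    msg <- c(msg, paste0("colData lacks: ", paste(miss, collapse = ", ")))
  if (anyDuplicated(rownames(object)))
    msg <- c(msg, "duplicate gene ids")
  if (length(msg)) msg else TRUE
})

#' Construct a CountDataset
#'
#' @param counts genes x samples matrix of nonnegative integer counts with
#'   gene ids as rownames and sample ids as colnames.
#' @param geneLengths numeric vector of gene lengths in bp, named by gene id
#'   or in row order of `counts`.
#' @param sampleInfo data.frame with one row per sample (rownames or a
#'   `sample_id` column) and columns `treatment` (FBZ/FLU/UNT), `breed`,
#'   `sex`, `batch`.
#' @param traits optional data.frame of PK parameters (columns among
#'   `r paste(pkTraitNames(), collapse = ", ")`), one row per sample with PK
#'   estimates; samples absent from it get `NA` traits.
#' @param annotation optional data.frame `gene_id`, `term_id`, `term_name`
#'   kept in `metadata()` for enrichment.
#' @return A [CountDataset-class] object.
#' @export
CountDataset <- function(counts, geneLengths, sampleInfo, traits = NULL,
                         annotation = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must have gene ids as rownames and sample ids as colnames")
  if (!is.null(names(geneLengths)))
    geneLengths <- geneLengths[rownames(counts)]
  if (length(geneLengths) != nrow(counts))
    stop("geneLengths does not cover every gene")
  if (!is.null(sampleInfo$sample_id)) {
    rownames(sampleInfo) <- sampleInfo$sample_id
    sampleInfo$sample_id <- NULL
  }
  sampleInfo <- sampleInfo[colnames(counts), , drop = FALSE]
  cd <- DataFrame(sampleInfo)
  cd$batch <- factor(cd$batch)
  for (tn in pkTraitNames()) cd[[tn]] <- NA_real_
  if (!is.null(traits)) {
    if (!is.null(traits$sample_id)) {
      rownames(traits) <- traits$sample_id
      traits$sample_id <- NULL
    }
    shared <- intersect(rownames(traits), colnames(counts))
    for (tn in intersect(colnames(traits), pkTraitNames()))
      cd[shared, tn] <- as.numeric(traits[shared, tn])
  }
  se <- SummarizedExperiment(
    assays = list(counts = counts),
    rowData = DataFrame(length_bp = as.numeric(geneLengths),
                        row.names = rownames(counts)),
    colData = cd)
  if (!is.null(annotation)) metadata(se)$annotation <- annotation
  new("CountDataset", se)
}

#' Normalization factors
#'
#' Per-sample library sizes, TMM scaling factors (geometric mean 1) and the
#' effective library sizes (`librarySize * tmmFactor`) used by CPM/RPKM.
#'
#' @name NormalizationFactors-class
#' @exportClass NormalizationFactors
setClass("NormalizationFactors", representation(
  librarySizes = "numeric",
  tmmFactors = "numeric",
  effectiveSizes = "numeric"))

setValidity("NormalizationFactors", function(object) {
  msg <- character()
  if (any(object@tmmFactors <= 0)) msg <- c(msg, "tmm factors must be > 0")
  if (abs(mean(log(object@tmmFactors))) > 1e-8)
    msg <- c(msg, "tmm factors must have geometric mean 1")
  if (any(abs(object@effectiveSizes -
              object@librarySizes * object@tmmFactors) > 1e-6))
    msg <- c(msg, "effectiveSizes must equal librarySizes * tmmFactors")
  if (length(msg)) msg else TRUE
})

#' Normalized expression matrix
#'
#' A genes x samples real matrix tagged with its scale (one of
#' CPM, log2CPM, RPKM, log2RPKM, batch_adjusted_log2RPKM,
#' batch_adjusted_log2CPM) and the ordered list of transforms that produced
#' it.
#'
#' @name ExprMatrix-class
#' @exportClass ExprMatrix
setClass("ExprMatrix", representation(
  values = "matrix",
  scale = "character",
  provenance = "character"))

setValidity("ExprMatrix", function(object) {
  msg <- character()
  if (anyNA(object@values)) msg <- c(msg, "missing values not allowed")
  if (is.null(rownames(object@values)) || is.null(colnames(object@values)))
    msg <- c(msg, "gene and sample labels are required")
  if (!object@scale %in% validScales())
    msg <- c(msg, paste0("unknown scale '", object@scale, "'"))
  if (length(msg)) msg else TRUE
})

#' Construct an ExprMatrix
#'
#' @param values genes x samples numeric matrix with dimnames.
#' @param scale scale tag (see [ExprMatrix-class]).
#' @param provenance ordered character vector of applied transforms.
#' @return An [ExprMatrix-class].
#' @export
ExprMatrix <- function(values, scale, provenance = scale) {
  new("ExprMatrix", values = values, scale = scale, provenance = provenance)
}

#' Unsigned weighted co-expression network
#'
#' Holds the soft-threshold power, the unsigned adjacency
#' (`|cor|^beta`, diagonal 1), the TOM dissimilarity, the average-linkage
#' dendrogram, module labels (color names, `"grey"` = unassigned), merged
#' module eigengenes (samples x modules) and the soft-threshold scan table.
#'
#' @name CoexpressionNetwork-class
#' @exportClass CoexpressionNetwork
setClass("CoexpressionNetwork", representation(
  geneIds = "character",
  beta = "numeric",
  adjacency = "matrix",
  tomDiss = "matrix",
  dendrogram = "ANY",
  labels = "character",
  eigengenes = "matrix",
  varExplained = "numeric",
  scan = "data.frame"))

setValidity("CoexpressionNetwork", function(object) {
  msg <- character()
  if (length(object@labels) != length(object@geneIds))
    msg <- c(msg, "one label per gene required")
  a <- object@adjacency
  if (nrow(a) && max(abs(a - t(a))) > 1e-12)
    msg <- c(msg, "adjacency must be symmetric")
  if (nrow(object@tomDiss) && any(abs(diag(object@tomDiss)) > 1e-12))
    msg <- c(msg, "TOM dissimilarity must have zero diagonal")
  if (length(msg)) msg else TRUE
})

#' Simulation configuration
#'
#' Parameters of the synthetic liver RNA-seq generator. Defaults emulate the
#' study design this package models: ~12,000 genes, 20 treated + 20 untreated
#' samples per drug arm, 5 batches, planted co-expression modules whose latent
#' factors track PK parameters, a fraction of treatment-DE genes per module,
#' and multiplicative batch effects.
#'
#' @name SimulationConfig-class
#' @exportClass SimulationConfig
setClass("SimulationConfig", representation(
  nGenes = "numeric",
  nTreated = "numeric",
  nUntreated = "numeric",
  nBatches = "numeric",
  moduleSpecs = "data.frame",
  deFraction = "numeric",
  deLog2FC = "numeric",
  dispShape = "numeric",
  dispRate = "numeric",
  batchSD = "numeric",
  lengthRange = "numeric",
  nTerms = "numeric",
  termEnrichment = "data.frame",
  treatment = "character",
  seed = "numeric"))

setValidity("SimulationConfig", function(object) {
  msg <- character()
  ms <- object@moduleSpecs
  if (nrow(ms)) {
    if (sum(ms$nGenes) > object@nGenes)
      msg <- c(msg, "module gene counts exceed nGenes")
    if (any(ms$strength < 0 | ms$strength > 1))
      msg <- c(msg, "latent factor strength must be in [0,1]")
    if (any(abs(ms$traitTarget) > 1))
      msg <- c(msg, "trait correlation targets must be in [-1,1]")
    if (any(ms$connGain < 0))
      msg <- c(msg, "connectivity gain must be >= 0")
  }
  if (object@deFraction < 0 || object@deFraction > 1)
    msg <- c(msg, "deFraction must be in [0,1]")
  if (object@dispShape <= 0 || object@dispRate <= 0)
    msg <- c(msg, "dispersion gamma parameters must be positive")
  if (object@batchSD < 0) msg <- c(msg, "batchSD must be >= 0")
  if (length(object@lengthRange) != 2 || any(object@lengthRange <= 0))
    msg <- c(msg, "lengthRange must be two positive bounds")
  if (nrow(object@termEnrichment)) {
    f <- object@termEnrichment$fraction
    if (any(f < 0 | f > 1)) msg <- c(msg, "enrichment fractions in [0,1]")
  }
  if (length(msg)) msg else TRUE
})

#' Ground truth of a simulated dataset
#'
#' @name GroundTruth-class
#' @exportClass GroundTruth
setClass("GroundTruth", representation(
  moduleAssignment = "character",
  deGenes = "character",
  traitLoadings = "data.frame",
  latentFactors = "matrix",
  batchSummary = "data.frame"))

setValidity("GroundTruth", function(object) {
  msg <- character()
  if (!all(object@deGenes %in% names(object@moduleAssignment)))
    msg <- c(msg, "deGenes outside the gene universe")
  if (length(msg)) msg else TRUE
})
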