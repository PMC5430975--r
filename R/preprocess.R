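#' Trimmed mean of M-values normalization factors
#'
#' Computes per-sample TMM scaling factors and effective library sizes.
#' The reference sample defaults to the one whose upper-quartile CPM is
#' closest to the mean upper quartile. Gene-wise log ratios (M) and average
#' log abundances (A) against the reference are trimmed (top/bottom 30% by
#' M, 5% by A) and the factor is `2^` the inverse-variance-weighted mean of
#' the remaining M values; factors are rescaled to geometric mean 1.
#' The computation is delegated to edgeR's TMM implementation.
#'
#' @param dataset a [CountDataset-class] (or plain counts matrix).
#' @param referenceSample optional sample id (or index) used as reference.
#' @return A [NormalizationFactors-class].
#' @export
tmmFactors <- function(dataset, referenceSample = NULL) {
  cnt <- if (is(dataset, "CountDataset")) counts(dataset) else
    as.matrix(dataset)
  if (ncol(cnt) < 2) stop("TMM requires at least 2 samples")
  lib <- colSums(cnt)
  if (any(lib == 0))
    stop("zero library size for sample(s): ",
         paste(colnames(cnt)[lib == 0], collapse = ", "))
  refCol <- NULL
  if (!is.null(referenceSample)) {
    refCol <- if (is.character(referenceSample))
      match(referenceSample, colnames(cnt)) else as.integer(referenceSample)
    if (is.na(refCol)) stop("unknown reference sample")
  } else {
    f75 <- apply(cnt, 2, stats::quantile, probs = 0.75) / lib
    refCol <- which.min(abs(f75 - mean(f75)))
  }
  refExpressed <- cnt[, refCol] > 0
  for (j in seq_len(ncol(cnt))) {
    if (j == refCol) next
    if (!any(cnt[, j] > 0 & refExpressed))
      stop(sprintf("sample %s shares no expressed genes with the reference",
                   colnames(cnt)[j]))
  }
  f <- edgeR::calcNormFactors(cnt, lib.size = lib, method = "TMM",
                              refColumn = refCol)
  f <- f / exp(mean(log(f)))  # geometric mean exactly 1
  names(f) <- colnames(cnt)
  new("NormalizationFactors", librarySizes = lib, tmmFactors = f,
      effectiveSizes = lib * f)
}

unitFactors <- function(cnt) {
  lib <- colSums(cnt)
  new("NormalizationFactors", librarySizes = lib,
      tmmFactors = stats::setNames(rep(1, ncol(cnt)), colnames(cnt)),
      effectiveSizes = lib)
}

#' Counts per million
#'
#' `cpm(g,s) = counts(g,s) / effectiveSize(s) * 1e6`.
#'
#' @param dataset a [CountDataset-class].
#' @param factors a [NormalizationFactors-class]; `NULL` uses raw library
#'   sizes (all TMM factors 1).
#' @return An [ExprMatrix-class] on the CPM scale.
#' @export
computeCPM <- function(dataset, factors = NULL) {
  cnt <- counts(dataset)
  if (is.null(factors)) factors <- unitFactors(cnt)
  eff <- effectiveSizes(factors)
  if (any(eff <= 0))
    stop("nonpositive effective library size for sample(s): ",
         paste(colnames(cnt)[eff <= 0], collapse = ", "))
  ExprMatrix(sweep(cnt, 2, eff, "/") * 1e6, "CPM", "CPM")
}

#' Reads per kilobase per million
#'
#' `rpkm(g,s) = counts(g,s) * 1e9 / (effectiveSize(s) * length_bp(g))`.
#'
#' @inheritParams computeCPM
#' @return An [ExprMatrix-class] on the RPKM scale.
#' @export
computeRPKM <- function(dataset, factors = NULL) {
  cnt <- counts(dataset)
  len <- geneLengths(dataset)
  if (anyNA(len))
    stop("missing gene length for: ",
         paste(utils::head(names(len)[is.na(len)], 5), collapse = ", "))
  if (is.null(factors)) factors <- unitFactors(cnt)
  eff <- effectiveSizes(factors)
  v <- sweep(cnt, 2, eff, "/") * 1e9
  v <- sweep(v, 1, len, "/")
  ExprMatrix(v, "RPKM", "RPKM")
}

#' Low-expression gene filter
#'
#' Keeps genes with CPM strictly above `minCPM` in at least `minSamples`
#' samples. The filter is applied to the full sample set (all arms jointly)
#' before any per-arm analysis.
#'
#' @param cpm an [ExprMatrix-class] on the CPM scale.
#' @param minCPM CPM threshold (strict inequality).
#' @param minSamples minimum number of samples exceeding it.
#' @return Character vector of retained gene ids.
#' @export
filterLowExpression <- function(cpm, minCPM = 1, minSamples = 5) {
  stopifnot(is(cpm, "ExprMatrix"))
  if (exprScale(cpm) != "CPM")
    stop("filterLowExpression expects a CPM-scale ExprMatrix")
  v <- exprValues(cpm)
  if (minSamples > ncol(v))
    stop(sprintf("minSamples (%d) exceeds sample count (%d)",
                 minSamples, ncol(v)))
  rownames(v)[rowSums(v > minCPM) >= minSamples]
}

#' Log2 transform with a prior count
#'
#' @param expr an [ExprMatrix-class] with nonnegative values.
#' @param prior prior count added before taking log2 (default 1, which maps
#'   0 to 0).
#' @return An [ExprMatrix-class] on the corresponding log2 scale.
#' @export
log2Transform <- function(expr, prior = 1) {
  stopifnot(is(expr, "ExprMatrix"))
  v <- exprValues(expr)
  if (any(v < 0)) stop("log2Transform requires nonnegative values")
  sc <- switch(exprScale(expr), CPM = "log2CPM", RPKM = "log2RPKM",
               stop("log2Transform expects CPM or RPKM input"))
  ExprMatrix(log2(v + prior), sc, c(provenance(expr),
                                    sprintf("log2(x + %g)", prior)))
}

#' Remove batch effects from log expression
#'
#' Per gene, a least-squares fit on the preserved biological design plus
#' sum-to-zero batch indicators; only the fitted batch component is
#' subtracted, so biological group means are untouched. Delegated to
#' limma's removeBatchEffect.
#'
#' @param expr a log-scale [ExprMatrix-class].
#' @param batch per-sample batch labels.
#' @param design optional design matrix of biological effects to preserve
#'   (default intercept only).
#' @return A batch-adjusted [ExprMatrix-class].
#' @export
batchAdjust <- function(expr, batch, design = NULL) {
  stopifnot(is(expr, "ExprMatrix"))
  if (!grepl("log2", exprScale(expr)))
    stop("batchAdjust expects log-scale input")
  v <- exprValues(expr)
  batch <- droplevels(factor(batch))
  if (length(batch) != ncol(v))
    stop("one batch label per sample required")
  newScale <- if (grepl("RPKM", exprScale(expr)))
    "batch_adjusted_log2RPKM" else "batch_adjusted_log2CPM"
  if (nlevels(batch) < 2)
    return(ExprMatrix(v, newScale, c(provenance(expr), "batch_adjust")))
  if (is.null(design)) design <- matrix(1, ncol(v), 1)
  stats::contrasts(batch) <- stats::contr.sum(nlevels(batch))
  bx <- stats::model.matrix(~batch)[, -1, drop = FALSE]
  X <- cbind(design, bx)
  if (qr(X)$rank < ncol(X))
    stop("batch is confounded with a preserved design column ",
         "(rank-deficient joint design)")
  adj <- limma::removeBatchEffect(v, batch = batch, design = design)
  ExprMatrix(adj, newScale, c(provenance(expr), "batch_adjust"))
}

#' Classical MDS on the top-SD genes
#'
#' Selects the `nTop` genes with the largest across-sample standard
#' deviation, computes pairwise Euclidean distances between samples and
#' applies classical (Torgerson) metric MDS via double-centering and
#' eigendecomposition.
#'
#' @param expr an [ExprMatrix-class] (typically log2 CPM).
#' @param nTop number of highest-SD genes used (default 500).
#' @param nDims number of coordinates returned.
#' @return data.frame `sample_id`, `Dim1..DimK`, with attribute
#'   `varExplained` giving each axis's share of the positive spectrum.
#' @export
mdsTopSD <- function(expr, nTop = 500, nDims = 2) {
  stopifnot(is(expr, "ExprMatrix"))
  v <- exprValues(expr)
  if (nTop > nrow(v))
    stop(sprintf("nTop (%d) exceeds gene count (%d)", nTop, nrow(v)))
  if (nDims > ncol(v) - 1)
    stop(sprintf("nDims (%d) exceeds sample count - 1 (%d)",
                 nDims, ncol(v) - 1))
  sds <- apply(v, 1, stats::sd)
  top <- order(sds, decreasing = TRUE)[seq_len(nTop)]
  d <- stats::dist(t(v[top, , drop = FALSE]))
  fit <- stats::cmdscale(d, k = nDims, eig = TRUE)
  pts <- fit$points
  if (ncol(pts) < nDims)  # degenerate spectra: pad exact-zero axes
    pts <- cbind(pts, matrix(0, nrow(pts), nDims - ncol(pts)))
  colnames(pts) <- paste0("Dim", seq_len(nDims))
  out <- data.frame(sample_id = colnames(v), pts, row.names = NULL)
  pos <- pmax(fit$eig, 0)
  attr(out, "varExplained") <- (pos / sum(pos))[seq_len(nDims)]
  out
}
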