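#' Unsigned adjacency matrix
#'
#' `a_ij = |pearson(x_i, x_j)|^beta`, diagonal 1. Constant genes have no
#' defined correlation and are dropped with a warning (or an error in
#' strict mode).
#'
#' @param expr an [ExprMatrix-class] or genes x samples matrix.
#' @param beta soft-threshold power.
#' @param strict error instead of dropping constant genes.
#' @param type `"unsigned"` (default, `|r|^beta`) or `"signed"`
#'   (`((1 + r)/2)^beta`, which suppresses negative correlations).
#' @return symmetric adjacency matrix in \[0,1\].
#' @export
adjacencyMatrix <- function(expr, beta, strict = FALSE,
                            type = c("unsigned", "signed")) {
  type <- match.arg(type)
  v <- if (is(expr, "ExprMatrix")) exprValues(expr) else as.matrix(expr)
  if (ncol(v) < 3) stop("adjacency requires at least 3 samples")
  sds <- apply(v, 1, stats::sd)
  if (any(sds == 0)) {
    bad <- rownames(v)[sds == 0]
    if (strict) stop("constant gene(s): ", paste(bad, collapse = ", "))
    warning("dropping constant gene(s): ", paste(bad, collapse = ", "))
    v <- v[sds > 0, , drop = FALSE]
  }
  r <- stats::cor(t(v))
  a <- if (type == "unsigned") abs(r)^beta else ((1 + r) / 2)^beta
  diag(a) <- 1
  a
}

scaleFreeFit <- function(k, nBins = 10) {
  k <- k[is.finite(k)]
  br <- seq(min(k), max(k), length.out = nBins + 1)
  bin <- cut(k, breaks = br, include.lowest = TRUE)
  counts <- tabulate(bin, nbins = nBins)
  meank <- tapply(k, bin, mean)
  ok <- counts > 0 & is.finite(meank) & meank > 0
  if (sum(ok) < 3) return(list(r2 = NA_real_, slope = NA_real_))
  x <- log10(meank[ok])
  y <- log10(counts[ok])
  fit <- stats::lm(y ~ x)
  slope <- stats::coef(fit)[2]
  r2 <- summary(fit)$r.squared
  list(r2 = -sign(slope) * r2, slope = unname(slope))
}

#' Soft-threshold power scan (scale-free topology criterion)
#'
#' For each candidate power the unsigned adjacency is formed, connectivities
#' `k_i = sum_j a_ij` (j != i) are binned into 10 equal-width bins, and
#' log10(bin frequency) is regressed on log10(mean bin connectivity); the
#' signed fit index is `-sign(slope) * R^2`. The chosen power is the
#' smallest candidate reaching `targetR2`, otherwise the candidate
#' maximizing the signed index. Candidates with fewer than 3 nonempty bins
#' are flagged (NA) and excluded from the choice.
#'
#' @param expr an [ExprMatrix-class] or genes x samples matrix.
#' @param powers candidate powers.
#' @param targetR2 signed R^2 target (default 0.90).
#' @return list with `scan` (data.frame power, r2_signed, slope, mean_k,
#'   median_k) and `power` (the chosen beta).
#' @export
pickSoftThreshold <- function(expr, powers = 1:20, targetR2 = 0.90) {
  if (length(powers) < 2) stop("need at least 2 candidate powers")
  v <- if (is(expr, "ExprMatrix")) exprValues(expr) else as.matrix(expr)
  absr <- abs(stats::cor(t(v)))
  diag(absr) <- 0
  scan <- data.frame(power = powers, r2_signed = NA_real_,
                     slope = NA_real_, mean_k = NA_real_,
                     median_k = NA_real_)
  for (i in seq_along(powers)) {
    a <- absr^powers[i]
    k <- rowSums(a)
    sf <- scaleFreeFit(k)
    scan$r2_signed[i] <- sf$r2
    scan$slope[i] <- sf$slope
    scan$mean_k[i] <- mean(k)
    scan$median_k[i] <- stats::median(k)
  }
  usable <- which(!is.na(scan$r2_signed))
  if (!length(usable)) stop("no candidate power produced >= 3 nonempty bins")
  hit <- usable[scan$r2_signed[usable] >= targetR2]
  power <- if (length(hit)) powers[min(hit)] else
    powers[usable[which.max(scan$r2_signed[usable])]]
  list(scan = scan, power = power)
}

#' Topological overlap similarity
#'
#' With self-connections excluded, `L_ij = sum_u a_iu a_uj` (u != i,j) and
#' `k_i = sum_u a_iu`; `TOM_ij = (L_ij + a_ij) / (min(k_i,k_j) + 1 - a_ij)`,
#' diagonal 1. The clustering input is `1 - TOM`.
#'
#' @param adjacency symmetric matrix in \[0,1\], diagonal 1.
#' @return TOM similarity matrix.
#' @export
tomSimilarity <- function(adjacency) {
  a <- as.matrix(adjacency)
  if (max(abs(a - t(a))) > 1e-8) stop("adjacency must be symmetric")
  a0 <- a
  diag(a0) <- 0
  L <- a0 %*% a0          # (i,j) entry sums over all u != i,j automatically
  k <- rowSums(a0)
  denom <- outer(k, k, pmin) + 1 - a0
  tom <- (L + a0) / denom
  diag(tom) <- 1
  dimnames(tom) <- dimnames(a)
  tom
}

#' Average-linkage (UPGMA) clustering of a dissimilarity matrix
#'
#' @param diss square symmetric matrix with zero diagonal (e.g. 1 - TOM).
#' @return an [stats::hclust] object.
#' @export
averageLinkage <- function(diss) {
  d <- as.matrix(diss)
  if (anyNA(d)) stop("dissimilarity contains NA")
  stats::hclust(stats::as.dist(d), method = "average")
}

#' Static tree cut into modules
#'
#' Cuts the dendrogram at `cutHeight` (default 0.99 x the maximum merge
#' height); connected subtrees below the cut with at least `minModuleSize`
#' members become modules, named by size rank from a fixed color palette
#' ("turquoise", "blue", "brown", ...); everything else is "grey". Ties in
#' size are broken by the lexicographically smallest member gene id, so
#' labels are stable under gene reordering.
#'
#' @param dendrogram an [stats::hclust] over the genes.
#' @param minModuleSize minimum module size (default 30).
#' @param cutHeight static cut height; `NULL` uses 0.99 x max height.
#' @return named character vector of module labels, one per gene.
#' @export
cutModules <- function(dendrogram, minModuleSize = 30, cutHeight = NULL) {
  maxH <- max(dendrogram$height)
  if (is.null(cutHeight)) cutHeight <- 0.99 * maxH
  if (cutHeight <= 0 || cutHeight > maxH)
    stop(sprintf("cutHeight must be in (0, %g]", maxH))
  cl <- stats::cutree(dendrogram, h = cutHeight)
  genes <- dendrogram$labels
  if (is.null(genes)) genes <- as.character(seq_along(cl))
  sizes <- table(cl)
  keep <- names(sizes)[sizes >= minModuleSize]
  labels <- rep("grey", length(cl))
  if (length(keep)) {
    minGene <- vapply(keep, function(cid)
      min(genes[cl == cid]), character(1))
    ord <- keep[order(-as.integer(sizes[keep]), minGene)]
    pal <- moduleColorPalette(length(ord))
    for (i in seq_along(ord)) labels[cl == ord[i]] <- pal[i]
  }
  stats::setNames(labels, genes)
}

#' Module eigengenes (first principal components)
#'
#' Each gene is standardized across samples; the module eigengene is the
#' first right-singular vector of the module's gene x sample block
#' (unit-norm sample scores), sign-flipped so it correlates nonnegatively
#' with the module's mean standardized expression. Constant genes are
#' dropped with a warning.
#'
#' @param expr an [ExprMatrix-class] or genes x samples matrix.
#' @param labels named module labels (from [cutModules()]).
#' @param includeGrey also compute an eigengene for the grey set.
#' @return list with `eigengenes` (samples x modules matrix) and
#'   `varExplained` (named numeric).
#' @export
moduleEigengenes <- function(expr, labels, includeGrey = FALSE) {
  v <- if (is(expr, "ExprMatrix")) exprValues(expr) else as.matrix(expr)
  mods <- setdiff(unique(labels), if (includeGrey) character(0) else "grey")
  mods <- sort(mods)
  me <- matrix(NA_real_, ncol(v), length(mods),
               dimnames = list(colnames(v), mods))
  ve <- stats::setNames(numeric(length(mods)), mods)
  for (m in mods) {
    rows <- names(labels)[labels == m]
    x <- v[rows, , drop = FALSE]
    sds <- apply(x, 1, stats::sd)
    if (any(sds == 0)) {
      warning(sprintf("module %s: dropping constant gene(s) %s", m,
                      paste(rows[sds == 0], collapse = ", ")))
      x <- x[sds > 0, , drop = FALSE]
      sds <- sds[sds > 0]
    }
    xs <- (x - rowMeans(x)) / sds
    sv <- svd(xs, nu = 0, nv = 1)
    e <- sv$v[, 1]
    if (stats::cor(e, colMeans(xs)) < 0) e <- -e
    me[, m] <- e
    ve[m] <- sv$d[1]^2 / sum(sv$d^2)
  }
  list(eigengenes = me, varExplained = ve)
}

#' Merge modules with highly correlated eigengenes
#'
#' Eigengenes are clustered by `1 - cor` with average linkage; groups
#' merging below `cutHeight` (default 0.15, i.e. r > 0.85) are combined,
#' the merged module keeping the label of its largest member. Eigengenes
#' are recomputed and the procedure iterates to a fixed point.
#'
#' @param expr expression used to recompute eigengenes.
#' @param labels named module labels.
#' @param cutHeight merge height on the 1 - cor scale.
#' @param maxIter safety bound on merge rounds.
#' @return list with `labels`, `eigengenes`, `varExplained`.
#' @export
mergeCloseModules <- function(expr, labels, cutHeight = 0.15,
                              maxIter = 10) {
  for (it in seq_len(maxIter)) {
    meObj <- moduleEigengenes(expr, labels)
    me <- meObj$eigengenes
    if (ncol(me) < 2) break
    d <- 1 - stats::cor(me)
    hc <- stats::hclust(stats::as.dist(d), method = "average")
    grp <- stats::cutree(hc, h = cutHeight)
    if (max(table(grp)) == 1) break
    for (gid in unique(grp)) {
      members <- colnames(me)[grp == gid]
      if (length(members) < 2) next
      sizes <- vapply(members, function(m) sum(labels == m), numeric(1))
      target <- members[which.max(sizes)]
      labels[labels %in% members] <- target
    }
  }
  meObj <- moduleEigengenes(expr, labels)
  list(labels = labels, eigengenes = meObj$eigengenes,
       varExplained = meObj$varExplained)
}

#' Build the full unsigned co-expression network
#'
#' Runs the complete construction: soft-threshold selection (unless `beta`
#' is given), adjacency, TOM dissimilarity, average-linkage clustering,
#' static tree cut with minimum module size, eigengene computation and
#' eigengene-correlation merging.
#'
#' @param expr an [ExprMatrix-class] or genes x samples matrix
#'   (typically batch-adjusted log2 RPKM).
#' @param beta soft power; `NULL` selects it by the scale-free criterion.
#' @param powers,targetR2 passed to [pickSoftThreshold()].
#' @param minModuleSize,cutHeight passed to [cutModules()].
#' @param mergeCutHeight passed to [mergeCloseModules()].
#' @return a [CoexpressionNetwork-class].
#' @export
buildNetwork <- function(expr, beta = NULL, powers = 1:20, targetR2 = 0.90,
                         minModuleSize = 30, cutHeight = NULL,
                         mergeCutHeight = 0.15) {
  v <- if (is(expr, "ExprMatrix")) exprValues(expr) else as.matrix(expr)
  scan <- data.frame()
  if (is.null(beta)) {
    ps <- pickSoftThreshold(v, powers = powers, targetR2 = targetR2)
    beta <- ps$power
    scan <- ps$scan
  }
  a <- adjacencyMatrix(v, beta)
  v <- v[rownames(a), , drop = FALSE]  # constant genes may have dropped
  dissTom <- 1 - tomSimilarity(a)
  dend <- averageLinkage(dissTom)
  dend$labels <- rownames(a)
  labels <- cutModules(dend, minModuleSize = minModuleSize,
                       cutHeight = cutHeight)
  merged <- mergeCloseModules(v, labels, cutHeight = mergeCutHeight)
  new("CoexpressionNetwork",
      geneIds = rownames(a), beta = as.numeric(beta), adjacency = a,
      tomDiss = dissTom, dendrogram = dend,
      labels = unname(merged$labels), eigengenes = merged$eigengenes,
      varExplained = merged$varExplained, scan = scan)
}
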