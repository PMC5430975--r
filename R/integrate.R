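#' Module eigengene - PK trait correlations
#'
#' Pairwise-complete Pearson correlations between module eigengenes and PK
#' parameters over the samples carrying both (in this design, the treated
#' animals: untreated animals have no PK estimates). Two-sided p-values use
#' the Student-t transform with n - 2 df. Constant traits are reported as
#' NA with a reason.
#'
#' @param eigengenes samples x modules matrix (see [moduleEigengenes()]).
#' @param traits samples x traits data.frame/matrix; rows matched on names.
#' @return data.frame `module`, `trait`, `r`, `p`, `n`, `note`.
#' @export
moduleTraitCorrelations <- function(eigengenes, traits) {
  traits <- as.data.frame(traits)
  shared <- intersect(rownames(eigengenes), rownames(traits))
  if (length(shared) < 3)
    stop("need at least 3 samples with both eigengenes and traits")
  me <- eigengenes[shared, , drop = FALSE]
  tr <- traits[shared, , drop = FALSE]
  out <- expand.grid(module = colnames(me), trait = colnames(tr),
                     stringsAsFactors = FALSE)
  out$r <- NA_real_; out$p <- NA_real_; out$n <- NA_integer_
  out$note <- ""
  for (i in seq_len(nrow(out))) {
    x <- me[, out$module[i]]
    y <- tr[, out$trait[i]]
    ok <- !is.na(x) & !is.na(y)
    out$n[i] <- sum(ok)
    if (sum(ok) < 3) { out$note[i] <- "fewer than 3 paired samples"; next }
    if (stats::sd(y[ok]) == 0) { out$note[i] <- "constant trait"; next }
    r <- stats::cor(x[ok], y[ok])
    out$r[i] <- r
    out$p[i] <- corPValue(r, sum(ok))
  }
  out
}

#' Module membership (kME)
#'
#' Correlation of each gene's expression profile with every module
#' eigengene (own and cross-module), with two-sided t-based p-values.
#'
#' @param expr an [ExprMatrix-class] or genes x samples matrix.
#' @param eigengenes samples x modules matrix.
#' @return list with matrices `kme` and `p` (genes x modules).
#' @export
moduleMembership <- function(expr, eigengenes) {
  v <- if (is(expr, "ExprMatrix")) exprValues(expr) else as.matrix(expr)
  shared <- intersect(colnames(v), rownames(eigengenes))
  if (length(shared) < 3) stop("need at least 3 shared samples")
  kme <- stats::cor(t(v[, shared, drop = FALSE]),
                    eigengenes[shared, , drop = FALSE])
  n <- length(shared)
  p <- apply(kme, c(1, 2), corPValue, n = n)
  list(kme = kme, p = p)
}

#' Three-filter module selection
#'
#' A module is selected when, on its best trait, `|r| > rMin` (strict) and
#' `p < pMax` (strict), and at least `deFracMin` of its genes are
#' differentially expressed (FDR < `fdrMax`) in the arm's
#' treated-vs-untreated contrast. The grey (unassigned) set is excluded.
#'
#' @param traitTable output of [moduleTraitCorrelations()].
#' @param deResults DE table for the arm (from [runDE()]).
#' @param labels named module labels.
#' @param rMin,pMax,deFracMin,fdrMax filter thresholds (defaults 0.30,
#'   0.10, 0.10, 0.05).
#' @return data.frame `module`, `best_trait`, `r`, `p`, `de_fraction`,
#'   `n_genes`, `selected`.
#' @export
selectModules <- function(traitTable, deResults, labels, rMin = 0.30,
                          pMax = 0.10, deFracMin = 0.10, fdrMax = 0.05) {
  mods <- setdiff(unique(labels), "grey")
  if (!all(c("gene_id", "fdr") %in% colnames(deResults)))
    stop("deResults must carry gene_id and fdr for this arm")
  sig <- deResults$gene_id[deResults$fdr < fdrMax]
  out <- data.frame(module = sort(mods), best_trait = NA_character_,
                    r = NA_real_, p = NA_real_, de_fraction = NA_real_,
                    n_genes = NA_integer_, selected = FALSE,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nrow(out))) {
    m <- out$module[i]
    rows <- traitTable[traitTable$module == m & !is.na(traitTable$r), ,
                       drop = FALSE]
    genes <- names(labels)[labels == m]
    out$n_genes[i] <- length(genes)
    out$de_fraction[i] <- mean(genes %in% sig)
    if (nrow(rows)) {
      best <- rows[which.max(abs(rows$r)), ]
      out$best_trait[i] <- best$trait
      out$r[i] <- best$r
      out$p[i] <- best$p
      out$selected[i] <- abs(best$r) > rMin && best$p < pMax &&
        out$de_fraction[i] >= deFracMin
    }
  }
  out
}
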