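#' Term enrichment of a module against the expressed background
#'
#' One-sided hypergeometric (Fisher-exact upper tail) tests: with
#' `N = |background|`, `K` genes of the background annotated to the term,
#' `n` module genes, and `x` of them annotated,
#' `p = P(X >= x), X ~ Hypergeometric(N, K, n)`. The annotation is first
#' intersected with the background (the expressed genes); empty terms are
#' dropped. FDR is Benjamini-Hochberg across the terms tested for the
#' module.
#'
#' @param moduleGenes gene ids of the module (must lie in `background`).
#' @param annotation data.frame `gene_id`, `term_id` and optionally
#'   `term_name`.
#' @param background expressed-gene universe.
#' @return data.frame `term_id`, `term_name`, `overlap`, `module_size`,
#'   `term_size`, `background_size`, `pvalue`, `fdr`, sorted by p.
#' @export
enrichmentTest <- function(moduleGenes, annotation, background) {
  moduleGenes <- unique(moduleGenes)
  background <- unique(background)
  if (!all(moduleGenes %in% background))
    stop("module genes outside the background universe: ",
         paste(utils::head(setdiff(moduleGenes, background), 5),
               collapse = ", "))
  ann <- annotation[annotation$gene_id %in% background, , drop = FALSE]
  if (!nrow(ann)) stop("no annotated genes in the background")
  sets <- split(ann$gene_id, ann$term_id)
  sets <- lapply(sets, unique)
  sets <- sets[lengths(sets) > 0]
  names <- if ("term_name" %in% colnames(ann))
    vapply(split(as.character(ann$term_name), ann$term_id)[names(sets)],
           `[`, character(1), 1)
  else stats::setNames(names(sets), names(sets))
  N <- length(background)
  n <- length(moduleGenes)
  out <- data.frame(
    term_id = names(sets),
    term_name = unname(names),
    overlap = vapply(sets, function(s)
      length(intersect(s, moduleGenes)), integer(1)),
    module_size = n,
    term_size = lengths(sets),
    background_size = N,
    row.names = NULL, stringsAsFactors = FALSE)
  out$pvalue <- stats::phyper(out$overlap - 1, out$term_size,
                              N - out$term_size, n, lower.tail = FALSE)
  out$fdr <- bhFDR(out$pvalue)
  out[order(out$pvalue, out$term_id), , drop = FALSE]
}

#' Enrichment across modules
#'
#' Runs [enrichmentTest()] for each non-grey module; `fdrScope = "global"`
#' recomputes FDR across every (module, term) test instead of per module.
#'
#' @param labels named module labels.
#' @param annotation data.frame `gene_id`, `term_id`, `term_name`.
#' @param background expressed-gene universe.
#' @param modules module names (default all non-grey).
#' @param fdrScope "module" (default) or "global".
#' @return data.frame with a `module` column prepended.
#' @export
moduleEnrichment <- function(labels, annotation, background,
                             modules = NULL,
                             fdrScope = c("module", "global")) {
  fdrScope <- match.arg(fdrScope)
  if (is.null(modules)) modules <- setdiff(sort(unique(labels)), "grey")
  out <- NULL
  for (m in modules) {
    genes <- names(labels)[labels == m]
    res <- enrichmentTest(genes, annotation, background)
    out <- rbind(out, cbind(module = m, res))
  }
  if (!is.null(out) && fdrScope == "global") out$fdr <- bhFDR(out$pvalue)
  out
}
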