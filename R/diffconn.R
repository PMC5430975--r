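#' Scaled within-module connectivity for one condition
#'
#' Restricts the unsigned adjacency (same soft power as the main network)
#' to the module's genes within one condition's samples; a gene's
#' connectivity is its summed adjacency to the other module genes, divided
#' by the within-network maximum so values lie in \[0,1\] with max 1.
#'
#' @param expr condition-specific [ExprMatrix-class] or matrix
#'   (samples of one condition only).
#' @param moduleGenes gene ids of the module.
#' @param beta soft-threshold power shared with the main network.
#' @return named numeric vector of scaled connectivities.
#' @export
scaledConnectivity <- function(expr, moduleGenes, beta) {
  v <- if (is(expr, "ExprMatrix")) exprValues(expr) else as.matrix(expr)
  if (length(moduleGenes) < 2) stop("need at least 2 module genes")
  missing <- setdiff(moduleGenes, rownames(v))
  if (length(missing))
    stop("module genes absent from expression: ",
         paste(utils::head(missing, 5), collapse = ", "))
  if (ncol(v) < 3) stop("need at least 3 samples in the condition")
  a <- adjacencyMatrix(v[moduleGenes, , drop = FALSE], beta)
  diag(a) <- 0
  k <- rowSums(a)
  if (max(k) == 0) stop("all-zero adjacency: scaling divisor is zero")
  k / max(k)
}

#' Differential connectivity and hub calling
#'
#' `deltaK = k_treated - k_untreated` per gene; positive values mean the
#' gene is more connected in the treated network. With
#' `hubOn = "delta"` (default) a gene is a hub when `|deltaK|` exceeds
#' `hubThreshold`; `hubOn = "raw"` instead flags genes whose scaled
#' connectivity exceeds the threshold in either condition.
#'
#' @param kTreated,kUntreated named scaled connectivities over the same
#'   gene set.
#' @param hubThreshold hub threshold (default 0.6).
#' @param hubOn "delta" or "raw".
#' @return data.frame `gene_id`, `k_treated`, `k_untreated`, `delta_k`,
#'   `hub`.
#' @export
differentialConnectivity <- function(kTreated, kUntreated,
                                     hubThreshold = 0.6,
                                     hubOn = c("delta", "raw")) {
  hubOn <- match.arg(hubOn)
  if (!setequal(names(kTreated), names(kUntreated)))
    stop("treated and untreated connectivity cover different gene sets")
  kUntreated <- kUntreated[names(kTreated)]
  dk <- kTreated - kUntreated
  hub <- if (hubOn == "delta") abs(dk) > hubThreshold else
    pmax(kTreated, kUntreated) > hubThreshold
  data.frame(gene_id = names(kTreated), k_treated = unname(kTreated),
             k_untreated = unname(kUntreated), delta_k = unname(dk),
             hub = unname(hub), row.names = NULL)
}

# Asymptotic two-sided Kolmogorov p with the standard effective-n correction.
ksAsymptoticP <- function(D, n1, n2) {
  if (D <= 0) return(1)
  ne <- n1 * n2 / (n1 + n2)
  lambda <- (sqrt(ne) + 0.12 + 0.11 / sqrt(ne)) * D
  kk <- seq_len(100)
  p <- 2 * sum((-1)^(kk - 1) * exp(-2 * kk^2 * lambda^2))
  min(1, max(0, p))
}

#' Two-sample Kolmogorov-Smirnov comparison of connectivity distributions
#'
#' `D = sup_x |F_treated(x) - F_untreated(x)|` over the pooled support of
#' the two step CDFs, with the asymptotic Kolmogorov p-value
#' (effective-n corrected). Degenerate all-equal inputs yield D computed on
#' the step CDFs (no NaN).
#'
#' @param kTreated,kUntreated numeric vectors (scaled connectivities).
#' @return data.frame `D`, `pvalue`, `mean_k_treated`, `mean_k_untreated`,
#'   `mean_diff`.
#' @export
ksCompare <- function(kTreated, kUntreated) {
  x <- as.numeric(kTreated)
  y <- as.numeric(kUntreated)
  if (anyNA(x) || anyNA(y)) stop("connectivities must not contain NA")
  pts <- sort(unique(c(x, y)))
  Fx <- vapply(pts, function(q) mean(x <= q), numeric(1))
  Fy <- vapply(pts, function(q) mean(y <= q), numeric(1))
  D <- max(abs(Fx - Fy))
  data.frame(D = D, pvalue = ksAsymptoticP(D, length(x), length(y)),
             mean_k_treated = mean(x), mean_k_untreated = mean(y),
             mean_diff = mean(x) - mean(y))
}

#' Per-module differential connectivity analysis
#'
#' For each selected module, computes scaled connectivity in the treated
#' and untreated expression matrices (same beta), the per-gene differential
#' connectivity with hub flags, and the KS comparison of the two
#' connectivity distributions.
#'
#' @param exprTreated,exprUntreated condition-specific expression
#'   ([ExprMatrix-class] or matrix).
#' @param labels named module labels.
#' @param modules module names to analyse (default: all non-grey).
#' @param beta shared soft power.
#' @param hubThreshold,hubOn passed to [differentialConnectivity()].
#' @return list with data.frames `connectivity` (module column prepended)
#'   and `ks` (one row per module).
#' @export
moduleDifferentialConnectivity <- function(exprTreated, exprUntreated,
                                           labels, modules = NULL, beta,
                                           hubThreshold = 0.6,
                                           hubOn = "delta") {
  if (is.null(modules)) modules <- setdiff(sort(unique(labels)), "grey")
  connAll <- NULL
  ksAll <- NULL
  for (m in modules) {
    genes <- names(labels)[labels == m]
    kt <- scaledConnectivity(exprTreated, genes, beta)
    ku <- scaledConnectivity(exprUntreated, genes, beta)
    dc <- differentialConnectivity(kt, ku, hubThreshold, hubOn)
    ks <- ksCompare(kt, ku)
    connAll <- rbind(connAll, cbind(module = m, dc))
    ksAll <- rbind(ksAll, cbind(module = m, ks))
  }
  list(connectivity = connAll, ks = ksAll)
}
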