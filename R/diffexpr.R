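#' Design matrices for treatment contrasts
#'
#' `scheme = "overall"` builds intercept + treated indicator + batch terms
#' (treated = any non-UNT treatment). `scheme = "by_breed"` / `"by_sex"`
#' build one cell mean per (group x treated) combination plus batch terms,
#' supporting the within-group interaction contrasts
#' (TreatedA - UntreatedA) - (TreatedB - UntreatedB). Columns made aliased
#' by the batch layout are dropped (with a message) so the returned matrix
#' is full column rank.
#'
#' @param samples data.frame with `treatment` and `batch` (plus `breed` /
#'   `sex` for the grouped schemes).
#' @param scheme one of "overall", "by_breed", "by_sex".
#' @return numeric design matrix with labelled columns; attribute
#'   `"cells"` names the cell-mean columns for the grouped schemes.
#' @export
buildDesign <- function(samples, scheme = c("overall", "by_breed",
                                            "by_sex")) {
  scheme <- match.arg(scheme)
  if (is.null(samples$treatment) || is.null(samples$batch))
    stop("samples must provide treatment and batch labels")
  treated <- samples$treatment != "UNT"
  batch <- droplevels(factor(samples$batch))
  bx <- if (nlevels(batch) > 1)
    stats::model.matrix(~batch)[, -1, drop = FALSE] else
    matrix(0, length(batch), 0)
  if (scheme == "overall") {
    X <- cbind(Intercept = 1, treated = as.numeric(treated), bx)
  } else {
    grp <- if (scheme == "by_breed") samples$breed else samples$sex
    if (is.null(grp)) stop("samples lack the grouping column for ", scheme)
    cell <- factor(paste(grp, ifelse(treated, "TRT", "UNT"), sep = "."))
    cm <- stats::model.matrix(~0 + cell)
    colnames(cm) <- sub("^cell", "", colnames(cm))
    X <- cbind(cm, bx)
    attr(X, "cells") <- colnames(cm)
  }
  q <- qr(X)
  if (q$rank < ncol(X)) {
    drop <- q$pivot[seq.int(q$rank + 1L, ncol(X))]
    if (any(seq_len(ncol(X) - ncol(bx)) %in% drop))
      stop("design is rank-deficient in treatment/cell columns: ",
           paste(colnames(X)[drop], collapse = ", "))
    message("dropping aliased batch column(s): ",
            paste(colnames(X)[drop], collapse = ", "))
    cells <- attr(X, "cells")
    X <- X[, -drop, drop = FALSE]
    attr(X, "cells") <- cells
  }
  rownames(X) <- rownames(samples)
  X
}

nbLogLik <- function(y, mu, phi) {
  mu <- pmax(mu, 1e-10)
  if (phi < 1e-8) sum(stats::dpois(y, mu, log = TRUE))
  else sum(stats::dnbinom(y, size = 1 / phi, mu = mu, log = TRUE))
}

# One-gene IRLS at fixed dispersion; a Poisson fit provides starting values
# and the fallback when the NB iterations diverge (flagged, not fatal).
nbGlmFitOne <- function(y, design, off, phi, ctl) {
  pois <- suppressWarnings(stats::glm.fit(design, y,
                                          family = stats::poisson(),
                                          offset = off, control = ctl))
  if (phi < 1e-8)
    return(list(coefficients = pois$coefficients,
                fitted.values = pois$fitted.values,
                converged = isTRUE(pois$converged)))
  fam <- MASS::negative.binomial(theta = 1 / phi, link = "log")
  fit <- tryCatch(
    suppressWarnings(stats::glm.fit(design, y, family = fam, offset = off,
                                    control = ctl,
                                    etastart = log(pmax(pois$fitted.values,
                                                        1e-10)))),
    error = function(e) NULL)
  if (is.null(fit))
    return(list(coefficients = pois$coefficients,
                fitted.values = pois$fitted.values, converged = FALSE))
  list(coefficients = fit$coefficients, fitted.values = fit$fitted.values,
       converged = isTRUE(fit$converged))
}

#' Moment-based dispersion estimation with shrinkage
#'
#' Per gene, a Poisson GLM is fit (log link, offsets = log effective library
#' sizes) and the NB dispersion is estimated by the pseudo-likelihood moment
#' equation on its Pearson residuals: phi solves
#' `sum (y - mu)^2 / (mu + phi mu^2) = n - p`, with one refit of the mean
#' under the estimated dispersion. The common dispersion is a 10%-trimmed
#' mean of the gene estimates; tagwise values shrink each gene toward the
#' common value on the log scale with a fixed weight (default 0.7 toward
#' common). All values are clamped to >= 1e-6.
#'
#' @param counts filtered genes x samples count matrix.
#' @param design design matrix from [buildDesign()].
#' @param factors a [NormalizationFactors-class] (or `NULL` for raw library
#'   sizes).
#' @param shrinkWeight weight on the common dispersion in \[0,1\].
#' @return list with `common`, `tagwise` (named per gene), `raw`
#'   (unshrunk gene estimates, clamped), `shrinkWeight`.
#' @export
estimateDispersionsMoM <- function(counts, design, factors = NULL,
                                   shrinkWeight = 0.7) {
  cnt <- as.matrix(counts)
  if (is.null(factors)) factors <- unitFactors(cnt)
  off <- log(effectiveSizes(factors))
  n <- ncol(cnt)
  p <- qr(design)$rank
  if (n - p < 1) stop("fewer than 1 residual degree of freedom")
  plMoment <- function(y) {
    fit <- suppressWarnings(stats::glm.fit(design, y,
                                           family = stats::poisson(),
                                           offset = off))
    mu <- pmax(fit$fitted.values, 1e-10)
    phi <- 0
    for (outer in 1:2) {
      r2 <- (y - mu)^2
      g <- function(ph) sum(r2 / (mu + ph * mu^2)) - (n - p)
      if (g(0) <= 0) phi <- 0
      else {
        hi <- 1
        while (g(hi) > 0 && hi < 1e3) hi <- hi * 2
        phi <- stats::uniroot(g, c(0, hi), tol = 1e-8)$root
      }
      if (outer == 1 && phi > 1e-8) {  # refit the mean under the NB weights
        fam <- MASS::negative.binomial(theta = 1 / phi)
        refit <- tryCatch(
          suppressWarnings(stats::glm.fit(design, y, family = fam,
                                          offset = off,
                                          etastart = log(mu))),
          error = function(e) NULL)
        if (!is.null(refit)) mu <- pmax(refit$fitted.values, 1e-10)
      }
    }
    phi
  }
  raw <- apply(cnt, 1, plMoment)
  floor <- 1e-6
  common <- max(mean(raw, trim = 0.1), floor)
  tagwise <- exp((1 - shrinkWeight) * log(pmax(raw, floor)) +
                 shrinkWeight * log(common))
  tagwise <- pmax(tagwise, floor)
  names(tagwise) <- rownames(cnt)
  list(common = common, tagwise = tagwise,
       raw = stats::setNames(pmax(raw, floor), rownames(cnt)),
       shrinkWeight = shrinkWeight)
}

#' Negative-binomial GLM fits at fixed dispersion
#'
#' Per gene, maximizes the NB log-likelihood (log link, fixed tagwise
#' dispersion) by iteratively reweighted least squares with effective
#' library sizes as offsets. Genes whose IRLS does not converge are flagged,
#' not fatal.
#'
#' @inheritParams estimateDispersionsMoM
#' @param dispersions result of [estimateDispersionsMoM()] (or a numeric
#'   vector of per-gene dispersions).
#' @return list with `coefficients` (genes x columns), `logLik`,
#'   `converged`, `dispersions`, `offset`, `design`.
#' @export
fitNbGlm <- function(counts, design, factors = NULL, dispersions) {
  cnt <- as.matrix(counts)
  if (is.null(factors)) factors <- unitFactors(cnt)
  off <- log(effectiveSizes(factors))
  phi <- if (is.list(dispersions)) dispersions$tagwise else dispersions
  phi <- rep_len(phi, nrow(cnt))
  coefs <- matrix(NA_real_, nrow(cnt), ncol(design),
                  dimnames = list(rownames(cnt), colnames(design)))
  ll <- numeric(nrow(cnt))
  conv <- logical(nrow(cnt))
  ctl <- stats::glm.control(epsilon = 1e-8, maxit = 50)
  for (g in seq_len(nrow(cnt))) {
    y <- cnt[g, ]
    fit <- nbGlmFitOne(y, design, off, phi[g], ctl)
    coefs[g, ] <- fit$coefficients
    conv[g] <- fit$converged
    ll[g] <- nbLogLik(y, fit$fitted.values, phi[g])
  }
  list(coefficients = coefs, logLik = ll, converged = conv,
       dispersions = phi, offset = off, design = design)
}

#' Likelihood-ratio test of a single-df contrast
#'
#' Refits each gene under the null `contrast %*% beta = 0` by
#' reparameterizing the design onto the contrast's null space; the statistic
#' is twice the log-likelihood difference, referred to chi-square with 1 df.
#' `log2fc` is the contrast applied to the coefficients, divided by log(2).
#'
#' @param fit result of [fitNbGlm()].
#' @param counts the count matrix the fit used.
#' @param contrast numeric contrast vector over design columns (or a named
#'   vector matching column labels).
#' @param label contrast label carried into the result table.
#' @return data.frame `gene_id`, `contrast`, `log2fc`, `stat`, `pvalue`,
#'   `fdr` (BH across the genes tested).
#' @export
lrtContrast <- function(fit, counts, contrast, label = "contrast") {
  cnt <- as.matrix(counts)
  X <- fit$design
  if (!is.null(names(contrast))) {
    cvec <- numeric(ncol(X))
    idx <- match(names(contrast), colnames(X))
    if (anyNA(idx))
      stop("contrast names absent from design: ",
           paste(names(contrast)[is.na(idx)], collapse = ", "))
    cvec[idx] <- contrast
  } else cvec <- rep_len(contrast, ncol(X))
  if (all(cvec == 0)) {
    stat <- rep(0, nrow(cnt))
    p <- rep(1, nrow(cnt))
    lfc <- rep(0, nrow(cnt))
  } else {
    # null-space reparameterization: columns orthogonal to the contrast
    Q <- qr.Q(qr(matrix(cvec, ncol = 1)), complete = TRUE)
    N <- Q[, -1, drop = FALSE]
    Xnull <- X %*% N
    if (qr(X)$rank - qr(Xnull)$rank != 1)
      stop("contrast is not estimable in this design")
    ctl <- stats::glm.control(epsilon = 1e-8, maxit = 50)
    llNull <- numeric(nrow(cnt))
    for (g in seq_len(nrow(cnt))) {
      y <- cnt[g, ]
      phi <- fit$dispersions[g]
      f0 <- nbGlmFitOne(y, Xnull, fit$offset, phi, ctl)
      llNull[g] <- nbLogLik(y, f0$fitted.values, phi)
    }
    stat <- pmax(2 * (fit$logLik - llNull), 0)
    p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
    lfc <- as.numeric(fit$coefficients %*% cvec) / log(2)
  }
  data.frame(gene_id = rownames(cnt), contrast = label, log2fc = lfc,
             stat = stat, pvalue = p, fdr = bhFDR(p), row.names = NULL)
}

#' Benjamini-Hochberg step-up FDR
#'
#' @param p vector of p-values in \[0,1\]; NA/NaN is an error.
#' @return monotone step-up adjusted values, capped at 1.
#' @export
bhFDR <- function(p) {
  if (anyNA(p)) stop("p-values must not contain NA/NaN")
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0,1]")
  stats::p.adjust(p, method = "BH")
}

#' One-call differential expression for a drug arm
#'
#' Subsets a dataset to one treated arm plus the untreated animals, builds
#' the requested design, estimates dispersions, fits the NB GLMs and tests
#' the treated-vs-untreated contrast (scheme "overall").
#'
#' @param dataset a [CountDataset-class] already filtered to expressed genes.
#' @param arm "FBZ" or "FLU".
#' @param factors optional [NormalizationFactors-class] computed on the full
#'   dataset; its per-sample effective sizes are subset to the arm.
#' @param shrinkWeight dispersion shrinkage weight.
#' @return data.frame as from [lrtContrast()], label `"<arm>_vs_UNT"`.
#' @export
runDE <- function(dataset, arm, factors = NULL, shrinkWeight = 0.7) {
  si <- sampleInfo(dataset)
  keep <- si$treatment %in% c(arm, "UNT")
  if (!any(si$treatment == arm))
    stop("no treated samples for arm ", arm)
  if (!any(si$treatment == "UNT")) stop("no untreated samples")
  cnt <- counts(dataset)[, keep, drop = FALSE]
  siA <- si[keep, , drop = FALSE]
  if (is.null(factors)) factors <- tmmFactors(counts(dataset))
  eff <- effectiveSizes(factors)[keep]
  fsub <- new("NormalizationFactors",
              librarySizes = eff, tmmFactors = rep(1, sum(keep)),
              effectiveSizes = eff)
  X <- buildDesign(siA, "overall")
  disp <- estimateDispersionsMoM(cnt, X, fsub, shrinkWeight = shrinkWeight)
  fit <- fitNbGlm(cnt, X, fsub, disp)
  ctr <- stats::setNames(1, "treated")
  lrtContrast(fit, cnt, ctr, label = paste0(arm, "_vs_UNT"))
}
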