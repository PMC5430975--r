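#' Accessors for the core classes
#'
#' `counts()` returns the raw count matrix; `geneLengths()` the bp lengths;
#' `sampleInfo()` the treatment/breed/sex/batch table; `pkTraits()` the PK
#' parameter table (`NA` rows for samples without PK estimates);
#' `geneAnnotation()` the gene-to-term table if attached.
#'
#' @param x a `CountDataset`, `NormalizationFactors`, `ExprMatrix`,
#'   `CoexpressionNetwork` or `GroundTruth` object as appropriate.
#' @param object object to display.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setMethod("counts", "CountDataset", function(object, ...) {
  SummarizedExperiment::assay(object, "counts")
})

#' @rdname accessors
#' @export
setMethod("geneLengths", "CountDataset", function(x) {
  stats::setNames(rowData(x)$length_bp, rownames(x))
})

#' @rdname accessors
#' @export
setMethod("sampleInfo", "CountDataset", function(x) {
  as.data.frame(colData(x)[, c("treatment", "breed", "sex", "batch")])
})

#' @rdname accessors
#' @export
setMethod("pkTraits", "CountDataset", function(x) {
  as.data.frame(colData(x)[, pkTraitNames()])
})

#' @rdname accessors
#' @export
setMethod("geneAnnotation", "CountDataset", function(x) {
  metadata(x)$annotation
})

#' @rdname accessors
#' @export
setMethod("libSizes", "NormalizationFactors", function(x) x@librarySizes)

#' @rdname accessors
#' @export
setMethod("normFactors", "NormalizationFactors", function(x) x@tmmFactors)

#' @rdname accessors
#' @export
setMethod("effectiveSizes", "NormalizationFactors",
          function(x) x@effectiveSizes)

#' @rdname accessors
#' @export
setMethod("exprValues", "ExprMatrix", function(x) x@values)

#' @rdname accessors
#' @export
setMethod("exprScale", "ExprMatrix", function(x) x@scale)

#' @rdname accessors
#' @export
setMethod("provenance", "ExprMatrix", function(x) x@provenance)

#' @rdname accessors
#' @export
setMethod("dim", "ExprMatrix", function(x) dim(x@values))

#' @rdname accessors
#' @export
setMethod("moduleLabels", "CoexpressionNetwork", function(x) {
  stats::setNames(x@labels, x@geneIds)
})

#' @rdname accessors
#' @export
setMethod("eigengenes", "CoexpressionNetwork", function(x) x@eigengenes)

#' @rdname accessors
#' @export
setMethod("softPower", "CoexpressionNetwork", function(x) x@beta)

#' @rdname accessors
#' @export
setMethod("moduleAssignment", "GroundTruth", function(x) x@moduleAssignment)

#' @rdname accessors
#' @export
setMethod("deGenes", "GroundTruth", function(x) x@deGenes)

#' @rdname accessors
#' @export
setMethod("traitLoadings", "GroundTruth", function(x) x@traitLoadings)

#' @rdname accessors
#' @export
setMethod("latentFactors", "GroundTruth", function(x) x@latentFactors)

#' @rdname accessors
#' @export
setMethod("show", "ExprMatrix", function(object) {
  cat("ExprMatrix:", nrow(object@values), "genes x", ncol(object@values),
      "samples, scale =", object@scale, "\n")
  cat("provenance:", paste(object@provenance, collapse = " -> "), "\n")
})

#' @rdname accessors
#' @export
setMethod("show", "NormalizationFactors", function(object) {
  cat("NormalizationFactors for", length(object@tmmFactors), "samples\n")
  cat("tmm factor range:",
      paste(signif(range(object@tmmFactors), 4), collapse = " .. "), "\n")
})

#' @rdname accessors
#' @export
setMethod("show", "CoexpressionNetwork", function(object) {
  tab <- table(object@labels)
  nmod <- sum(names(tab) != "grey")
  cat("CoexpressionNetwork:", length(object@geneIds), "genes, beta =",
      object@beta, "\n")
  cat(nmod, "modules (+",
      if ("grey" %in% names(tab)) tab[["grey"]] else 0,
      "grey/unassigned genes)\n")
})

#' @rdname accessors
#' @export
setMethod("show", "GroundTruth", function(object) {
  tab <- table(object@moduleAssignment)
  cat("GroundTruth:", length(object@moduleAssignment), "genes,",
      sum(names(tab) != "background"), "planted modules,",
      length(object@deGenes), "DE genes\n")
})

#' @rdname accessors
#' @export
setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig:", object@nGenes, "genes,", object@nTreated,
      "treated +", object@nUntreated, "untreated samples,",
      object@nBatches, "batches,", nrow(object@moduleSpecs),
      "planted modules, seed", object@seed, "\n")
})
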