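#' @importFrom BiocGenerics counts
NULL

#' @export
setGeneric("geneLengths", function(x) standardGeneric("geneLengths"))
#' @export
setGeneric("sampleInfo", function(x) standardGeneric("sampleInfo"))
#' @export
setGeneric("pkTraits", function(x) standardGeneric("pkTraits"))
#' @export
setGeneric("geneAnnotation", function(x) standardGeneric("geneAnnotation"))
#' @export
setGeneric("libSizes", function(x) standardGeneric("libSizes"))
#' @export
setGeneric("normFactors", function(x) standardGeneric("normFactors"))
#' @export
setGeneric("effectiveSizes", function(x) standardGeneric("effectiveSizes"))
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))
#' @export
setGeneric("exprScale", function(x) standardGeneric("exprScale"))
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))
#' @export
setGeneric("moduleLabels", function(x) standardGeneric("moduleLabels"))
#' @export
setGeneric("eigengenes", function(x) standardGeneric("eigengenes"))
#' @export
setGeneric("softPower", function(x) standardGeneric("softPower"))
#' @export
setGeneric("moduleAssignment", function(x) standardGeneric("moduleAssignment"))
#' @export
setGeneric("deGenes", function(x) standardGeneric("deGenes"))
#' @export
setGeneric("traitLoadings", function(x) standardGeneric("traitLoadings"))
#' @export
setGeneric("latentFactors", function(x) standardGeneric("latentFactors"))
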