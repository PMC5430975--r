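#' Read and write dataset bundles as TSV
#'
#' `writeDataset()` emits `counts.tsv`, `lengths.tsv`, `samples.tsv`,
#' `traits.tsv` (one row per sample with PK estimates; untreated animals,
#' which have none, are simply absent), `annotation.tsv` (if attached) and,
#' when `truth` is given, `truth.json`. `readDataset()` reads the same
#' dialects back into a [CountDataset-class]; the round trip is lossless.
#'
#' @param dataset a [CountDataset-class].
#' @param directory output/input directory.
#' @param truth optional [GroundTruth-class] written to `truth.json`.
#' @return `writeDataset()`: invisibly, the vector of files written.
#'   `readDataset()`: a [CountDataset-class].
#' @export
writeDataset <- function(dataset, directory, truth = NULL) {
  if (!dir.exists(directory))
    dir.create(directory, recursive = TRUE)
  wr <- function(df, file) {
    path <- file.path(directory, file)
    ok <- try(utils::write.table(df, path, sep = "\t", quote = FALSE,
                                 row.names = FALSE), silent = TRUE)
    if (inherits(ok, "try-error"))
      stop(sprintf("failed writing %s: %s", path, as.character(ok)))
    path
  }
  cnt <- counts(dataset)
  files <- c(
    wr(data.frame(gene_id = rownames(cnt), cnt, check.names = FALSE),
       "counts.tsv"),
    wr(data.frame(gene_id = rownames(cnt),
                  length_bp = unname(geneLengths(dataset))),
       "lengths.tsv"),
    wr(data.frame(sample_id = colnames(cnt), sampleInfo(dataset)),
       "samples.tsv"))
  tr <- pkTraits(dataset)
  keep <- rowSums(!is.na(tr)) > 0
  trOut <- data.frame(sample_id = rownames(tr)[keep])
  for (tn in pkTraitNames())
    trOut[[tn]] <- ifelse(is.na(tr[keep, tn]), "",
                          sprintf("%.17g", tr[keep, tn]))
  files <- c(files, wr(trOut, "traits.tsv"))
  ann <- geneAnnotation(dataset)
  if (!is.null(ann)) files <- c(files, wr(ann, "annotation.tsv"))
  if (!is.null(truth))
    files <- c(files, writeGroundTruth(truth,
                                       file.path(directory, "truth.json")))
  invisible(files)
}

#' @rdname writeDataset
#' @export
readDataset <- function(directory) {
  rd <- function(file, ...) {
    path <- file.path(directory, file)
    if (!file.exists(path))
      stop(sprintf("missing input file: %s", path))
    utils::read.delim(path, check.names = FALSE,
                      stringsAsFactors = FALSE, ...)
  }
  cntDf <- rd("counts.tsv")
  cnt <- as.matrix(cntDf[, -1, drop = FALSE])
  rownames(cnt) <- cntDf$gene_id
  storage.mode(cnt) <- "double"
  len <- rd("lengths.tsv")
  lengths <- stats::setNames(len$length_bp, len$gene_id)
  samp <- rd("samples.tsv")
  traits <- NULL
  if (file.exists(file.path(directory, "traits.tsv"))) {
    traits <- rd("traits.tsv", colClasses = c(sample_id = "character"))
    if (nrow(traits) == 0) traits <- NULL
    else for (tn in setdiff(colnames(traits), "sample_id"))
      traits[[tn]] <- as.numeric(traits[[tn]])
  }
  ann <- NULL
  if (file.exists(file.path(directory, "annotation.tsv"))) {
    ann <- rd("annotation.tsv")
    ann$term_name <- as.character(ann$term_name)
  }
  CountDataset(cnt, lengths, samp, traits = traits, annotation = ann)
}

#' Serialize / reload simulation ground truth
#'
#' @param truth a [GroundTruth-class].
#' @param path JSON file path.
#' @return `writeGroundTruth()`: the path, invisibly. `readGroundTruth()`:
#'   a [GroundTruth-class] equal to the one written.
#' @export
writeGroundTruth <- function(truth, path) {
  lf <- truth@latentFactors
  obj <- list(
    module_assignment = as.list(truth@moduleAssignment),
    de_genes = truth@deGenes,
    trait_loadings = truth@traitLoadings,
    latent_factors = list(modules = rownames(lf), samples = colnames(lf),
                          values = unname(lf)),
    batch_summary = truth@batchSummary)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = FALSE)
  invisible(path)
}

#' @rdname writeGroundTruth
#' @export
readGroundTruth <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  lfRaw <- obj$latent_factors
  nMod <- length(lfRaw$modules)
  lf <- matrix(0, nrow = nMod, ncol = length(lfRaw$samples),
               dimnames = list(lfRaw$modules, lfRaw$samples))
  if (nMod) lf[] <- as.matrix(lfRaw$values)
  tl <- as.data.frame(obj$trait_loadings)
  bs <- as.data.frame(obj$batch_summary)
  new("GroundTruth",
      moduleAssignment = unlist(obj$module_assignment),
      deGenes = as.character(unlist(obj$de_genes)),
      traitLoadings = tl,
      latentFactors = lf,
      batchSummary = bs)
}
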