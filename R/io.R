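# Plain-text serialization: peptide lists, catalogs as FASTA, predictor
# specs as JSON.

#' Read / write one-peptide-per-line text files
#'
#' @param path file path.
#' @return `readPeptides`: character vector of peptides.
#' @export
readPeptides <- function(path) {
  x <- readLines(path)
  x <- trimws(x)
  x[nzchar(x)]
}

#' @rdname readPeptides
#' @param peptides character vector.
#' @export
writePeptides <- function(peptides, path) {
  writeLines(peptides, path)
  invisible(path)
}

#' Write an allele catalog as FASTA
#'
#' @param catalog an [AlleleCatalog-class].
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
writeCatalogFasta <- function(catalog, path) {
  Biostrings::writeXStringSet(alleleSequences(catalog), path)
  invisible(path)
}

#' Read an allele catalog from FASTA
#'
#' Cluster assignments are not stored in FASTA; all alleles are placed in
#' cluster 1 unless a `cluster` vector is supplied.
#'
#' @param path FASTA path.
#' @param locus locus label.
#' @param cluster optional named integer cluster assignment.
#' @return An [AlleleCatalog-class].
#' @export
readCatalogFasta <- function(path, locus = "SYN", cluster = NULL) {
  seqs <- Biostrings::readAAStringSet(path)
  if (is.null(cluster))
    cluster <- setNames(rep(1L, length(seqs)), names(seqs))
  new("AlleleCatalog", locus = locus, sequences = seqs,
      cluster = as.integer(cluster[names(seqs)]) |>
        setNames(names(seqs)))
}

#' Serialize / restore a predictor spec as JSON
#'
#' @param spec a list from [predictorSpec()].
#' @param path JSON path.
#' @return `writePredictorSpec`: `path` invisibly; `readPredictorSpec`: the
#'   spec list.
#' @export
writePredictorSpec <- function(spec, path) {
  jsonlite::write_json(spec, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writePredictorSpec
#' @export
readPredictorSpec <- function(path) {
  spec <- jsonlite::read_json(path, simplifyVector = TRUE)
  predictorSpec(pocketPositions = spec$pocketPositions,
                pocketWeights = spec$pocketWeights,
                weightSD = spec$weightSD, squashMid = spec$squashMid,
                squashScale = spec$squashScale, seed = spec$seed)
}
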