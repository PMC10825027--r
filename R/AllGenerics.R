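# Generics and accessors.

#' Score peptides with a predictor
#'
#' The scoring contract every benchmark stage relies on: given an MHC protein
#' sequence and a character vector of peptides (length >= 9), return one
#' eluted-ligand-like score in \[0, 1\] per peptide, plus the reported 9-mer
#' binding core.  Methods exist for [PSSMPredictor-class] objects and for
#' plain R functions (which must accept `(mhcSeq, peptides)` and return either
#' a numeric vector of scores or a data.frame with columns `score` and
#' `core`).
#'
#' @param predictor a [PSSMPredictor-class], or a function.
#' @param mhcSeq single character string, the MHC protein sequence.
#' @param peptides character vector of peptide sequences.
#' @return data.frame with columns `score` (numeric in \[0,1\]) and `core`
#'   (character 9-mers).
#' @export
setGeneric("scorePeptides", function(predictor, mhcSeq, peptides)
  standardGeneric("scorePeptides"))

#' @rdname AlleleCatalog-class
#' @param x,object an `AlleleCatalog`.
#' @export
setGeneric("alleleSequences", function(x) standardGeneric("alleleSequences"))

#' @rdname AlleleCatalog-class
#' @export
setGeneric("alleleClusters", function(x) standardGeneric("alleleClusters"))

#' @rdname AlleleCatalog-class
#' @export
setGeneric("locusName", function(x) standardGeneric("locusName"))

#' @rdname EvaluationDataset-class
#' @param x,object an `EvaluationDataset`.
#' @export
setGeneric("peptideTable", function(x) standardGeneric("peptideTable"))

#' @rdname EvaluationDataset-class
#' @export
setGeneric("nVerified", function(x) standardGeneric("nVerified"))

#' @rdname EvaluationDataset-class
#' @export
setGeneric("spikeFraction", function(x) standardGeneric("spikeFraction"))

#' @rdname AlleleDistanceMatrix-class
#' @param x,object an `AlleleDistanceMatrix`.
#' @export
setGeneric("distanceMatrix", function(x) standardGeneric("distanceMatrix"))

## ---- accessors -------------------------------------------------------------

#' @rdname AlleleCatalog-class
#' @export
setMethod("alleleSequences", "AlleleCatalog", function(x) x@sequences)

#' @rdname AlleleCatalog-class
#' @export
setMethod("alleleClusters", "AlleleCatalog", function(x) x@cluster)

#' @rdname AlleleCatalog-class
#' @export
setMethod("locusName", "AlleleCatalog", function(x) x@locus)

#' @rdname AlleleCatalog-class
#' @export
setMethod("length", "AlleleCatalog", function(x) length(x@sequences))

#' @rdname AlleleCatalog-class
#' @export
setMethod("names", "AlleleCatalog", function(x) names(x@sequences))

#' @rdname EvaluationDataset-class
#' @export
setMethod("peptideTable", "EvaluationDataset", function(x) x@peptides)

#' @rdname EvaluationDataset-class
#' @export
setMethod("nVerified", "EvaluationDataset",
          function(x) sum(x@peptides$label == "verified"))

#' @rdname EvaluationDataset-class
#' @export
setMethod("spikeFraction", "EvaluationDataset", function(x) x@spikeFraction)

#' @rdname EvaluationDataset-class
#' @export
setMethod("length", "EvaluationDataset", function(x) nrow(x@peptides))

#' @rdname AlleleDistanceMatrix-class
#' @export
setMethod("distanceMatrix", "AlleleDistanceMatrix", function(x) x@distances)

## ---- show methods ----------------------------------------------------------

setMethod("show", "AlleleCatalog", function(object) {
  cat("AlleleCatalog of", length(object), "alleles, locus", object@locus,
      "\n  sequence length:",
      if (length(object)) Biostrings::width(object@sequences)[1L] else 0L,
      "\n  clusters:", length(unique(object@cluster)), "\n")
})

setMethod("show", "PSSMPredictor", function(object) {
  cat("PSSMPredictor (pocket-keyed synthetic PWM scorer)\n",
      " pocket positions:", paste(object@pocketPositions, collapse = " "), "\n",
      " squash: logistic(mid =", object@squashMid,
      ", scale =", object@squashScale, ")\n")
})

setMethod("show", "AlleleFrequencyTable", function(object) {
  cat("AlleleFrequencyTable, locus", object@locus, ":",
      nrow(object@frequencies), "populations x",
      ncol(object@frequencies), "alleles\n")
})

setMethod("show", "CoverageReport", function(object) {
  cat("CoverageReport, locus", object@locus,
      "(residual mass treated as", paste0(object@residualTreatment, ")\n"))
  print(head(object@table, 6L))
  if (nrow(object@table) > 6L) cat("  ...", nrow(object@table), "populations\n")
})

setMethod("show", "EvaluationDataset", function(object) {
  p <- object@peptides
  cat("EvaluationDataset for allele", object@allele, "\n ",
      nrow(p), "peptides (", sum(p$label == "verified"), "verified /",
      sum(p$label == "decoy"), "decoy ), spike fraction",
      object@spikeFraction, "\n  columns:",
      paste(colnames(p), collapse = ", "), "\n")
})

setMethod("show", "MotifPFM", function(object) {
  cat("MotifPFM:", ncol(object@matrix), "positions x 20 amino acids,",
      "pseudocount", object@pseudocount, "\n")
})

setMethod("show", "InformationCorrection", function(object) {
  cat("InformationCorrection: C = alpha + beta * I - mu\n",
      sprintf("  alpha = %.4f, beta = %.4f, mu = %.4f\n",
              object@alpha, object@beta, object@mu),
      " alleles:", length(object@correction), "\n")
})

setMethod("show", "AlleleDistanceMatrix", function(object) {
  cat("AlleleDistanceMatrix:", nrow(object@distances), "alleles,",
      object@convention, "self-max convention, raw-distance divisor",
      format(object@normalizer), "\n")
})

setMethod("show", "MDSEmbedding", function(object) {
  cat("MDSEmbedding:", nrow(object@points), "points in",
      ncol(object@points), "dimensions\n")
})

setMethod("show", "SensitivityProfile", function(object) {
  cat("SensitivityProfile for allele", object@allele, ":",
      length(object@residues), "residues scanned over", object@nPeptides,
      "peptides (k =", object@k, ",", object@mode, "mode)\n")
})
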