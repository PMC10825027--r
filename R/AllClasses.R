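# S4 classes for the benchmark framework.

#' AlleleCatalog: a clustered set of MHC protein sequences
#'
#' Holds equal-length MHC protein sequences (one per allele) together with the
#' cluster each allele was generated from.  Produced by [genAlleleCatalog()].
#'
#' @slot locus single character, locus label (e.g. `"A"`).
#' @slot sequences [Biostrings::AAStringSet] of equal width; names are the
#'   allele identifiers.
#' @slot cluster named integer vector, cluster index per allele.
#' @export
setClass("AlleleCatalog",
  slots = c(locus = "character", sequences = "AAStringSet", cluster = "integer"))

setValidity("AlleleCatalog", function(object) {
  msg <- character(0)
  ids <- names(object@sequences)
  if (length(object@locus) != 1L) msg <- c(msg, "locus must be a single string")
  if (is.null(ids) || anyDuplicated(ids))
    msg <- c(msg, "allele identifiers must be present and unique")
  if (length(object@sequences) > 0L &&
      length(unique(Biostrings::width(object@sequences))) != 1L)
    msg <- c(msg, "all sequences must have equal length")
  if (length(object@cluster) != length(object@sequences) ||
      !identical(names(object@cluster), ids))
    msg <- c(msg, "cluster must be named to match the sequences")
  if (length(msg)) msg else TRUE
})

#' PSSMPredictor: a deterministic pocket-keyed PWM predictor
#'
#' A synthetic eluted-ligand score predictor whose 9-mer-core position weight
#' matrix is a deterministic function of the residues at a fixed set of MHC
#' "pocket" positions.  The score of a peptide is the best sliding 9-mer
#' window sum of PWM weights, squashed to \[0, 1\] by a logistic map.  Because
#' the PWM depends only on pocket residues, ground truth for sensitivity
#' scanning is known exactly: substitutions outside the pockets cannot change
#' any score.
#'
#' @slot pocketPositions integer vector of length 9; MHC residue indices, one
#'   keying each core position.
#' @slot pocketWeights numeric vector of length 9; multiplier on each PWM
#'   column (dependence strength of the corresponding pocket).
#' @slot weightLUT numeric array `20 x 9 x 20` (pocket residue, core position,
#'   peptide residue) of base weights, drawn once from the spec seed.
#' @slot squashMid,squashScale logistic squash parameters: score =
#'   `1/(1 + exp(-(sum - squashMid)/squashScale))`.
#' @slot seed integer seed the lookup table was drawn from.
#' @slot seqLength MHC sequence length the predictor was built for.
#' @export
setClass("PSSMPredictor",
  slots = c(pocketPositions = "integer", pocketWeights = "numeric",
            weightLUT = "array", squashMid = "numeric", squashScale = "numeric",
            seed = "integer", seqLength = "integer"))

setValidity("PSSMPredictor", function(object) {
  msg <- character(0)
  if (length(object@pocketPositions) != 9L)
    msg <- c(msg, "exactly 9 pocket positions are required (one per core position)")
  if (any(object@pocketPositions < 1L) ||
      any(object@pocketPositions > object@seqLength))
    msg <- c(msg, "pocket positions must lie within [1, seqLength]")
  if (length(object@pocketWeights) != 9L || any(object@pocketWeights < 0))
    msg <- c(msg, "pocketWeights must be 9 nonnegative values")
  if (!identical(dim(object@weightLUT), c(20L, 9L, 20L)))
    msg <- c(msg, "weightLUT must be a 20 x 9 x 20 array")
  if (length(msg)) msg else TRUE
})

#' BackgroundModel: decoy peptide source
#'
#' Amino-acid background frequencies plus an optional proteome pool for
#' substring decoy sampling.
#'
#' @slot frequencies named numeric vector over the 20 amino acids, sums to 1.
#' @slot pool [Biostrings::AAStringSet] (possibly empty) of proteome sequences
#'   for substring sampling.
#' @export
setClass("BackgroundModel",
  slots = c(frequencies = "numeric", pool = "AAStringSet"))

setValidity("BackgroundModel", function(object) {
  f <- object@frequencies
  msg <- character(0)
  if (!identical(sort(names(f)), sort(AA_ALPHABET)))
    msg <- c(msg, "frequencies must be named by the 20 amino acids")
  if (any(f < 0) || abs(sum(f) - 1) > 1e-9)
    msg <- c(msg, "frequencies must be nonnegative and sum to 1")
  if (length(msg)) msg else TRUE
})

#' AlleleFrequencyTable: population x allele frequencies for one locus
#'
#' @slot locus single character.
#' @slot frequencies numeric matrix, rows = populations, cols = alleles;
#'   entries in \[0,1\], row sums at most 1 (residual mass may be unlisted).
#' @export
setClass("AlleleFrequencyTable",
  slots = c(locus = "character", frequencies = "matrix"))

setValidity("AlleleFrequencyTable", function(object) {
  f <- object@frequencies
  msg <- character(0)
  if (is.null(rownames(f)) || is.null(colnames(f)))
    msg <- c(msg, "frequency matrix needs population rownames and allele colnames")
  if (any(f < 0) || any(f > 1)) msg <- c(msg, "frequencies must lie in [0, 1]")
  if (nrow(f) > 0L && any(rowSums(f) > 1 + 1e-9))
    msg <- c(msg, "per-population frequencies must sum to at most 1")
  if (length(msg)) msg else TRUE
})

#' CoverageReport: uncovered-individual fractions for one locus
#'
#' @slot locus single character.
#' @slot table data.frame with columns `population`, `coveredMass`,
#'   `uncoveredFraction`.
#' @slot uncoveredAlleles character vector of alleles with positive frequency
#'   absent from the training set.
#' @slot residualTreatment `"covered"` or `"uncovered"`: how frequency mass of
#'   alleles missing from the table was treated.
#' @export
setClass("CoverageReport",
  slots = c(locus = "character", table = "data.frame",
            uncoveredAlleles = "character", residualTreatment = "character"))

setValidity("CoverageReport", function(object) {
  msg <- character(0)
  need <- c("population", "coveredMass", "uncoveredFraction")
  if (!all(need %in% names(object@table)))
    msg <- c(msg, "table must have population, coveredMass, uncoveredFraction")
  u <- object@table$uncoveredFraction
  if (length(u) && (any(u < -1e-12) || any(u > 1 + 1e-12)))
    msg <- c(msg, "uncovered fractions must lie in [0, 1]")
  if (!object@residualTreatment %in% c("covered", "uncovered"))
    msg <- c(msg, "residualTreatment must be 'covered' or 'uncovered'")
  if (length(msg)) msg else TRUE
})

#' EvaluationDataset: labeled binder + decoy peptides for one allele
#'
#' The central benchmark container: peptide records with `verified`/`decoy`
#' labels, filled in stage by stage with scores, binding cores, core weights,
#' fractional ranks and corrected ranks (columns appear as
#' [scoreDataset()], [fractionalRanks()], [coreWeights()] and
#' [applyCorrection()] are applied).
#'
#' @slot allele single character identifier.
#' @slot peptides [S4Vectors::DataFrame] with at least columns `peptide`
#'   (character) and `label` (`"verified"`/`"decoy"`).
#' @slot spikeFraction numeric, verified fraction the set was assembled at.
#' @export
setClass("EvaluationDataset",
  slots = c(allele = "character", peptides = "DataFrame",
            spikeFraction = "numeric"))

setValidity("EvaluationDataset", function(object) {
  msg <- character(0)
  p <- object@peptides
  if (!all(c("peptide", "label") %in% colnames(p)))
    msg <- c(msg, "peptides must have 'peptide' and 'label' columns")
  else {
    if (!all(p$label %in% c("verified", "decoy")))
      msg <- c(msg, "labels must be 'verified' or 'decoy'")
    if (nrow(p) && any(grepl(sprintf("[^%s]", paste(AA_ALPHABET, collapse = "")),
                             p$peptide)))
      msg <- c(msg, "peptides must use the 20-letter amino-acid alphabet")
  }
  if (length(object@spikeFraction) != 1L || object@spikeFraction <= 0 ||
      object@spikeFraction > 1)
    msg <- c(msg, "spikeFraction must be a single value in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' MotifPFM: position frequency matrix of a binding motif
#'
#' @slot matrix numeric 20 x L matrix (rows = amino acids alphabetical,
#'   columns = core positions); columns sum to 1, all entries positive after
#'   pseudocounting.
#' @slot pseudocount numeric, pseudocount per amino acid per column used in
#'   estimation.
#' @slot background named numeric vector q over the 20 amino acids.
#' @export
setClass("MotifPFM",
  slots = c(matrix = "matrix", pseudocount = "numeric", background = "numeric"))

setValidity("MotifPFM", function(object) {
  m <- object@matrix
  msg <- character(0)
  if (nrow(m) != 20L || !identical(rownames(m), AA_ALPHABET))
    msg <- c(msg, "matrix must have 20 rows named by the amino acids")
  if (ncol(m) < 1L) msg <- c(msg, "matrix needs at least one column")
  if (any(m <= 0)) msg <- c(msg, "all entries must be positive (apply a pseudocount)")
  if (any(abs(colSums(m) - 1) > 1e-9)) msg <- c(msg, "columns must sum to 1")
  q <- object@background
  if (!identical(names(q), AA_ALPHABET) || any(q <= 0))
    msg <- c(msg, "background must be strictly positive over the 20 amino acids")
  if (length(msg)) msg else TRUE
})

#' InformationCorrection: motif-information rank correction
#'
#' The fitted linear model of verified-peptide log10 ranks against motif
#' information, and the per-allele correction factors
#' `C_allele = alpha + beta * I_allele - mu` it implies.  Subtracting
#' `C_allele` from an allele's log ranks removes the linear information trend
#' while the `mu` re-centering keeps corrected values on the original scale.
#'
#' @slot alpha,beta regression intercept and slope.
#' @slot mu weighted grand mean of the pooled log10 ranks.
#' @slot information named numeric, per-allele motif information (bits).
#' @slot correction named numeric, per-allele correction factors.
#' @export
setClass("InformationCorrection",
  slots = c(alpha = "numeric", beta = "numeric", mu = "numeric",
            information = "numeric", correction = "numeric"))

setValidity("InformationCorrection", function(object) {
  msg <- character(0)
  expect <- object@alpha + object@beta * object@information - object@mu
  if (length(expect) && max(abs(expect - object@correction)) > 1e-9)
    msg <- c(msg, "correction must equal alpha + beta * I - mu")
  if (!identical(names(object@information), names(object@correction)))
    msg <- c(msg, "information and correction must share allele names")
  if (length(msg)) msg else TRUE
})

#' AlleleDistanceMatrix: normalized pairwise sequence or motif distances
#'
#' @slot distances symmetric nonnegative numeric matrix with unit maximum
#'   entry (after normalization) and allele dimnames.
#' @slot normalizer the raw-distance divisor that was applied.
#' @slot convention `"pairwise"` (self-max per pair, zero diagonal) or
#'   `"global"` (single global maximum similarity).
#' @export
setClass("AlleleDistanceMatrix",
  slots = c(distances = "matrix", normalizer = "numeric", convention = "character"))

setValidity("AlleleDistanceMatrix", function(object) {
  d <- object@distances
  msg <- character(0)
  if (nrow(d) != ncol(d) || is.null(rownames(d)) ||
      !identical(rownames(d), colnames(d)))
    msg <- c(msg, "distances must be square with matching dimnames")
  if (max(abs(d - t(d))) > 1e-12) msg <- c(msg, "distances must be symmetric")
  if (any(d < -1e-12)) msg <- c(msg, "distances must be nonnegative")
  if (length(msg)) msg else TRUE
})

#' MDSEmbedding: classical multidimensional scaling coordinates
#'
#' @slot points numeric matrix (alleles x k), centered at the origin.
#' @slot eig eigenvalues of the doubly-centered Gram matrix, descending.
#' @export
setClass("MDSEmbedding", slots = c(points = "matrix", eig = "numeric"))

setValidity("MDSEmbedding", function(object) {
  msg <- character(0)
  if (nrow(object@points) > 0L &&
      max(abs(colMeans(object@points))) > 1e-9)
    msg <- c(msg, "coordinates must be centered at the origin")
  if (is.unsorted(rev(object@eig))) msg <- c(msg, "eigenvalues must be descending")
  if (length(msg)) msg else TRUE
})

#' SensitivityProfile: per-residue substitution impact
#'
#' For each scanned MHC residue, the mean drop in predictor score over a
#' peptide set when the residue is replaced by its most disruptive
#' substitutions (the k lowest-scoring of the 19 alternatives).
#'
#' @slot allele single character identifier.
#' @slot residues integer vector of scanned residue indices (1-based).
#' @slot impact numeric vector, one impact per scanned residue
#'   (unmutated score minus mean of the k lowest mutated scores).
#' @slot k number of lowest-scoring substitutions averaged.
#' @slot nPeptides number of peptides scanned.
#' @slot mode `"per_peptide"` (k lowest chosen per peptide) or
#'   `"per_residue"` (k lowest mean-score substitutions).
#' @export
setClass("SensitivityProfile",
  slots = c(allele = "character", residues = "integer", impact = "numeric",
            k = "integer", nPeptides = "integer", mode = "character"))

setValidity("SensitivityProfile", function(object) {
  msg <- character(0)
  if (length(object@impact) != length(object@residues))
    msg <- c(msg, "one impact value per scanned residue is required")
  if (any(!is.finite(object@impact))) msg <- c(msg, "impacts must be finite")
  if (length(msg)) msg else TRUE
})
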