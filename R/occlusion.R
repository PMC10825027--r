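# Residue-substitution (occlusion-style) sensitivity scanning: substitute
# every MHC residue with each of the 19 alternatives, keep the k = 5 most
# disruptive substitutions, and report the mean score drop over a verified
# peptide set.

#' Residue-substitution sensitivity scan
#'
#' For each residue index in `residueRange`, builds the 19 mutant MHC
#' sequences differing only at that residue and scores the peptide set with
#' each.  In the default `"per_peptide"` mode, each peptide contributes its
#' unmutated score minus the mean of its `k` lowest mutated scores; the
#' residue's impact is the mean contribution over peptides.  In
#' `"per_residue"` mode the `k` substitutions with the lowest mean score over
#' all peptides are selected first, then averaged.  Positive impact means
#' substituting the residue lowers predicted binding, i.e. the predictor
#' relies on it.
#'
#' @param predictor a [PSSMPredictor-class] or function predictor.
#' @param mhcSeq MHC protein sequence (1-based residue numbering).
#' @param peptides nonempty character vector of verified peptides.
#' @param residueRange integer vector of residue indices to scan (default the
#'   whole sequence).
#' @param k number of lowest-scoring substitutions averaged (default 5,
#'   at most 19).
#' @param mode `"per_peptide"` (default) or `"per_residue"`.
#' @param allele identifier recorded in the profile.
#' @return A [SensitivityProfile-class].
#' @export
substitutionScan <- function(predictor, mhcSeq, peptides,
                             residueRange = NULL, k = 5L,
                             mode = c("per_peptide", "per_residue"),
                             allele = "unknown") {
  mode <- match.arg(mode)
  L <- nchar(mhcSeq)
  if (is.null(residueRange)) residueRange <- seq_len(L)
  residueRange <- as.integer(residueRange)
  if (any(residueRange < 1L) || any(residueRange > L))
    stop("residue range out of bounds [1, ", L, "]")
  if (k < 1L || k > 19L) stop("k must lie in [1, 19]")
  if (length(peptides) == 0L) stop("peptides must be nonempty")
  base <- scorePeptides(predictor, mhcSeq, peptides)$score
  res <- strsplit(mhcSeq, "", fixed = TRUE)[[1L]]
  impact <- numeric(length(residueRange))
  for (ri in seq_along(residueRange)) {
    r <- residueRange[ri]
    alts <- setdiff(AA_ALPHABET, res[r])
    # peptides x 19 matrix of mutated scores
    mut <- vapply(alts, function(a) {
      s <- res; s[r] <- a
      scorePeptides(predictor, paste(s, collapse = ""), peptides)$score
    }, numeric(length(peptides)))
    if (length(peptides) == 1L) mut <- matrix(mut, nrow = 1L)
    if (mode == "per_peptide") {
      lowMeans <- apply(mut, 1L, function(v) mean(sort(v)[seq_len(k)]))
      impact[ri] <- mean(base - lowMeans)
    } else {
      colAvg <- colMeans(mut)
      sel <- order(colAvg)[seq_len(k)]
      impact[ri] <- mean(base) - mean(colAvg[sel])
    }
  }
  new("SensitivityProfile", allele = allele, residues = residueRange,
      impact = impact, k = as.integer(k),
      nPeptides = length(peptides), mode = mode)
}

#' Rank residues by substitution impact
#'
#' @param profile a [SensitivityProfile-class].
#' @param topM optionally truncate to the `topM` highest-impact residues.
#' @return Integer vector of residue indices, impact descending, ties broken
#'   by residue index ascending.
#' @export
rankResidues <- function(profile, topM = NULL) {
  o <- order(-profile@impact, profile@residues)
  ranked <- profile@residues[o]
  if (!is.null(topM)) ranked <- ranked[seq_len(min(topM, length(ranked)))]
  ranked
}

#' Pocket-recovery metrics for a synthetic scan
#'
#' With a synthetic predictor the residues that matter are known exactly, so
#' a scan can be graded: precision of the top-`|pockets|` ranked residues
#' against the true pocket set, and the worst (largest) rank any true pocket
#' receives.
#'
#' @param ranked integer vector from [rankResidues()].
#' @param truePockets nonempty integer vector of ground-truth pocket residues.
#' @return List with `precisionAtM` and `worstPocketRank`.
#' @export
recoveryMetrics <- function(ranked, truePockets) {
  truePockets <- unique(as.integer(truePockets))
  if (length(truePockets) == 0L) stop("pocket set is empty")
  m <- length(truePockets)
  top <- ranked[seq_len(min(m, length(ranked)))]
  pos <- match(truePockets, ranked)
  list(precisionAtM = sum(top %in% truePockets) / m,
       worstPocketRank = if (anyNA(pos)) NA_integer_ else max(pos))
}

#' Write a sensitivity profile to TSV
#'
#' Columns: residue, impact, n_peptides.
#'
#' @param profile a [SensitivityProfile-class].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeSensitivityProfile <- function(profile, path) {
  df <- data.frame(residue = profile@residues, impact = profile@impact,
                   n_peptides = profile@nPeptides)
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
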