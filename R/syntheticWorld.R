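# Synthetic data universe: clustered allele catalogs, Dirichlet population
# frequencies, a deterministic pocket-keyed PWM predictor, and motif-driven
# binder / background decoy samplers.  Everything is seeded and reproducible.

#' Generate a clustered synthetic allele catalog
#'
#' Seeds one ancestral protein sequence per cluster (drawn from the background
#' amino-acid distribution) and derives each allele by independent per-site
#' substitutions, so alleles organise into sequence-space clusters the way HLA
#' alleles do.
#'
#' @param nAlleles number of alleles.
#' @param nClusters number of clusters (`<= nAlleles`).
#' @param seqLength MHC protein length (default 60).
#' @param mutationRate per-site substitution probability in `[0, 1)` applied
#'   to each allele relative to its cluster ancestor.
#' @param seed integer seed; the same seed reproduces the catalog exactly.
#' @param locus locus label stored in the catalog.
#' @param background amino-acid frequencies for the ancestral sequences.
#' @return An [AlleleCatalog-class].
#' @export
#' @examples
#' cat1 <- genAlleleCatalog(12, 3, seqLength = 60, mutationRate = 0.05, seed = 1)
#' cat1
genAlleleCatalog <- function(nAlleles, nClusters, seqLength = 60L,
                             mutationRate = 0.02, seed = NULL, locus = "SYN",
                             background = humanProteomeFrequencies()) {
  if (nAlleles < 1L || nClusters < 1L || nClusters > nAlleles)
    stop("need 1 <= nClusters <= nAlleles")
  if (mutationRate < 0 || mutationRate >= 1)
    stop("mutationRate must lie in [0, 1)")
  if (seqLength < 9L) stop("seqLength must be at least 9")
  withSeed(seed, {
    ancestors <- replicate(nClusters, sample(AA_ALPHABET, seqLength,
                                             replace = TRUE, prob = background),
                           simplify = FALSE)
    cluster <- sort(rep_len(seq_len(nClusters), nAlleles))
    seqs <- character(nAlleles)
    for (i in seq_len(nAlleles)) {
      s <- ancestors[[cluster[i]]]
      hit <- runif(seqLength) < mutationRate
      if (any(hit)) {
        # substitute with a uniformly chosen *different* residue
        for (j in which(hit)) {
          s[j] <- sample(setdiff(AA_ALPHABET, s[j]), 1L)
        }
      }
      seqs[i] <- paste(s, collapse = "")
    }
    ids <- sprintf("%s*%02d:%02d", locus, cluster,
                   stats::ave(seq_len(nAlleles), cluster, FUN = seq_along))
    new("AlleleCatalog", locus = locus,
        sequences = Biostrings::AAStringSet(setNames(seqs, ids)),
        cluster = setNames(as.integer(cluster), ids))
  })
}

#' Generate Dirichlet population allele frequencies
#'
#' Draws each population's allele-frequency vector from a symmetric Dirichlet
#' distribution over the catalog's alleles.  Small concentrations give the
#' realistic case of a few dominant alleles per population; very large
#' concentrations approach the uniform `1/nAlleles`.
#'
#' @param catalog an [AlleleCatalog-class].
#' @param nPopulations number of populations.
#' @param concentration Dirichlet concentration (> 0), default 0.5.
#' @param seed integer seed.
#' @return An [AlleleFrequencyTable-class]; rows sum to 1.
#' @export
genPopulationFrequencies <- function(catalog, nPopulations,
                                     concentration = 0.5, seed = NULL) {
  if (length(catalog) == 0L) stop("catalog is empty")
  if (concentration <= 0) stop("concentration must be positive")
  if (nPopulations < 1L) stop("nPopulations must be at least 1")
  withSeed(seed, {
    m <- t(replicate(nPopulations,
                     rdirichlet1(rep(concentration, length(catalog)))))
    dimnames(m) <- list(sprintf("pop%02d", seq_len(nPopulations)),
                        names(catalog))
    new("AlleleFrequencyTable", locus = locusName(catalog), frequencies = m)
  })
}

#' Specify a synthetic pocket-keyed predictor
#'
#' Bundles the parameters of the deterministic PWM predictor: which MHC
#' residues form the binding pocket (one per 9-mer core position), how
#' strongly each pocket position is weighted, and the logistic squash that
#' maps summed PWM scores to \[0, 1\].
#'
#' @param pocketPositions integer vector of length 9, MHC residue indices.
#' @param pocketWeights nonnegative multipliers per core position (default 1).
#' @param weightSD standard deviation of the base PWM weights.
#' @param squashMid,squashScale logistic parameters.
#' @param seed integer seed the weight lookup table is drawn from.
#' @return A plain list spec consumed by [buildPredictor()].
#' @export
predictorSpec <- function(pocketPositions, pocketWeights = rep(1, 9),
                          weightSD = 2, squashMid = 12, squashScale = 3,
                          seed = 42L) {
  list(pocketPositions = as.integer(pocketPositions),
       pocketWeights = as.numeric(pocketWeights),
       weightSD = weightSD, squashMid = squashMid,
       squashScale = squashScale, seed = as.integer(seed))
}

#' Build the synthetic predictor
#'
#' Materialises a [PSSMPredictor-class] from a spec: a `20 x 9 x 20` weight
#' lookup table is drawn once from the spec seed, and thereafter the PWM of
#' any MHC sequence is `LUT[pocket residue, core position, ] * pocketWeight`.
#' Identical pocket residues therefore give identical PWMs, and the score is
#' a deterministic function of (MHC sequence, peptide).
#'
#' @param catalog an [AlleleCatalog-class] (fixes the MHC sequence length the
#'   pocket positions are validated against).
#' @param spec a list from [predictorSpec()].
#' @return A [PSSMPredictor-class].
#' @export
buildPredictor <- function(catalog, spec) {
  seqLength <- if (length(catalog)) Biostrings::width(alleleSequences(catalog))[1L]
               else stop("catalog is empty")
  if (any(spec$pocketPositions < 1L) || any(spec$pocketPositions > seqLength))
    stop("pocket positions must lie within [1, ", seqLength, "]")
  lut <- withSeed(spec$seed,
                  array(stats::rnorm(20 * 9 * 20, sd = spec$weightSD),
                        dim = c(20L, 9L, 20L),
                        dimnames = list(AA_ALPHABET, NULL, AA_ALPHABET)))
  new("PSSMPredictor", pocketPositions = spec$pocketPositions,
      pocketWeights = spec$pocketWeights, weightLUT = lut,
      squashMid = spec$squashMid, squashScale = spec$squashScale,
      seed = spec$seed, seqLength = as.integer(seqLength))
}

#' Position weight matrix of an MHC sequence under the synthetic predictor
#'
#' @param predictor a [PSSMPredictor-class].
#' @param mhcSeq MHC protein sequence (length `seqLength`).
#' @return 20 x 9 numeric matrix of per-position residue weights.
#' @export
predictorPWM <- function(predictor, mhcSeq) {
  res <- strsplit(mhcSeq, "", fixed = TRUE)[[1L]]
  if (length(res) != predictor@seqLength)
    stop("MHC sequence length ", length(res), " != expected ",
         predictor@seqLength)
  pocketRes <- aaIndex(res[predictor@pocketPositions])
  if (anyNA(pocketRes)) stop("non-standard residue at a pocket position")
  pwm <- vapply(seq_len(9L), function(j)
    predictor@weightLUT[pocketRes[j], j, ] * predictor@pocketWeights[j],
    numeric(20L))
  rownames(pwm) <- AA_ALPHABET
  pwm
}

# Score a set of peptides against a PWM: best sliding 9-mer window sum,
# logistic-squashed; also returns the best window (the reported binding core).
.scoreAgainstPWM <- function(pwm, peptides, squashMid, squashScale) {
  if (length(peptides) == 0L)
    return(data.frame(score = numeric(0), core = character(0)))
  lens <- nchar(peptides)
  if (any(lens < 9L)) {
    bad <- which(lens < 9L)[1L]
    stop("peptide ", sQuote(peptides[bad]), " is shorter than the 9-mer core")
  }
  score <- numeric(length(peptides))
  corePos <- integer(length(peptides))
  for (L in unique(lens)) {
    sel <- which(lens == L)
    m <- peptideIntMatrix(peptides[sel])
    nWin <- L - 9L + 1L
    winScores <- matrix(0, nrow = length(sel), ncol = nWin)
    for (w in seq_len(nWin)) {
      s <- 0
      for (j in seq_len(9L)) s <- s + pwm[cbind(m[, w + j - 1L], j)]
      winScores[, w] <- s
    }
    best <- max.col(winScores, ties.method = "first")
    score[sel] <- winScores[cbind(seq_along(sel), best)]
    corePos[sel] <- best
  }
  data.frame(score = 1 / (1 + exp(-(score - squashMid) / squashScale)),
             core = substr(peptides, corePos, corePos + 8L),
             stringsAsFactors = FALSE)
}

#' @rdname scorePeptides
#' @export
setMethod("scorePeptides", "PSSMPredictor", function(predictor, mhcSeq, peptides) {
  pwm <- predictorPWM(predictor, mhcSeq)
  .scoreAgainstPWM(pwm, peptides, predictor@squashMid, predictor@squashScale)
})

#' @rdname scorePeptides
#' @export
setMethod("scorePeptides", "function", function(predictor, mhcSeq, peptides) {
  out <- predictor(mhcSeq, peptides)
  if (is.numeric(out))
    out <- data.frame(score = out,
                      core = substr(peptides, 1L, 9L),
                      stringsAsFactors = FALSE)
  if (!all(c("score", "core") %in% names(out)))
    stop("a function predictor must return scores or a data.frame with ",
         "'score' and 'core'")
  if (nrow(out) != length(peptides))
    stop("predictor returned ", nrow(out), " scores for ",
         length(peptides), " peptides")
  out[c("score", "core")]
})

#' Build a predictor from an external prediction table
#'
#' Adapter for externally computed predictions in NetMHCpan-style tabular
#' form: a data.frame with columns `peptide`, `score` and optionally `core`.
#' Returns a function predictor usable wherever the scoring contract is
#' expected; peptides absent from the table raise an error.
#'
#' @param table data.frame with columns `peptide`, `score`, optional `core`.
#' @return A function `(mhcSeq, peptides) -> data.frame(score, core)`.
#' @export
tablePredictor <- function(table) {
  if (!all(c("peptide", "score") %in% names(table)))
    stop("table needs 'peptide' and 'score' columns")
  if (anyDuplicated(table$peptide)) stop("duplicate peptides in table")
  core <- if ("core" %in% names(table)) table$core
          else substr(table$peptide, 1L, 9L)
  lookup <- setNames(seq_len(nrow(table)), table$peptide)
  function(mhcSeq, peptides) {
    i <- lookup[peptides]
    if (anyNA(i))
      stop("no external prediction for peptide ",
           sQuote(peptides[which(is.na(i))[1L]]))
    data.frame(score = table$score[i], core = core[i],
               stringsAsFactors = FALSE)
  }
}

#' Create a background (decoy) model
#'
#' @param frequencies named amino-acid frequency vector (defaults to the
#'   bundled human-proteome-like composition).
#' @param pool optional [Biostrings::AAStringSet] proteome for substring
#'   sampling.
#' @return A [BackgroundModel-class].
#' @export
backgroundModel <- function(frequencies = humanProteomeFrequencies(),
                            pool = Biostrings::AAStringSet()) {
  f <- frequencies[AA_ALPHABET]
  names(f) <- AA_ALPHABET
  if (anyNA(f)) stop("frequencies must cover all 20 amino acids")
  new("BackgroundModel", frequencies = f / sum(f), pool = pool)
}

#' Sample verified-binder-like peptides from a predictor's motif
#'
#' Draws peptide cores position-wise from the softmax of the allele-specific
#' PWM columns (so sampled peptides score highly under the same predictor),
#' pads to the requested length with background-distributed flanks, and
#' splits the flank length uniformly between N- and C-terminus.
#'
#' @param predictor a [PSSMPredictor-class].
#' @param mhcSeq MHC protein sequence of the allele.
#' @param n number of peptides.
#' @param lengthDist named probability vector over peptide lengths (names are
#'   lengths `>= 9`); default all 9-mers.
#' @param background a [BackgroundModel-class] for flank residues.
#' @param seed integer seed.
#' @return Character vector of `n` peptides.
#' @export
sampleBinders <- function(predictor, mhcSeq, n, lengthDist = c("9" = 1),
                          background = backgroundModel(), seed = NULL) {
  if (n <= 0L) stop("n must be positive")
  if (any(as.integer(names(lengthDist)) < 9L))
    stop("binder lengths must be at least the 9-mer core")
  pwm <- predictorPWM(predictor, mhcSeq)
  probs <- apply(pwm, 2L, function(col) { e <- exp(col - max(col)); e / sum(e) })
  withSeed(seed, {
    lens <- sampleLengths(n, lengthDist)
    coreMat <- vapply(seq_len(9L), function(j)
      sample(AA_ALPHABET, n, replace = TRUE, prob = probs[, j]),
      character(n))
    if (n == 1L) coreMat <- matrix(coreMat, nrow = 1L)
    cores <- apply(coreMat, 1L, paste, collapse = "")
    nFlank <- lens - 9L
    left <- vapply(nFlank, function(k) if (k > 0L) sample.int(k + 1L, 1L) - 1L
                   else 0L, integer(1L))
    right <- nFlank - left
    flank <- function(k) if (k > 0L)
      paste(sample(AA_ALPHABET, k, replace = TRUE,
                   prob = background@frequencies), collapse = "") else ""
    vapply(seq_len(n), function(i)
      paste0(flank(left[i]), cores[i], flank(right[i])), character(1L))
  })
}

#' Sample background decoy peptides
#'
#' Decoys are either i.i.d. residue strings from the background frequencies
#' (`mode = "iid"`, the random-amino-acid-string control) or substrings of
#' the proteome pool (`mode = "substring"`).  Lengths follow `lengthDist`
#' probabilistically, or `lengthCounts` exactly when a target histogram is
#' given (the class-II rule of matching the verified-peptide length
#' distribution).
#'
#' @param background a [BackgroundModel-class].
#' @param n number of decoys (ignored when `lengthCounts` is given).
#' @param lengthDist named probability vector over lengths.
#' @param lengthCounts named integer vector: exact number of decoys per
#'   length; overrides `n` and `lengthDist`.
#' @param mode `"iid"` or `"substring"`.
#' @param seed integer seed.
#' @return Character vector of decoy peptides.
#' @export
sampleDecoys <- function(background, n, lengthDist = c("9" = 1),
                         lengthCounts = NULL, mode = c("iid", "substring"),
                         seed = NULL) {
  mode <- match.arg(mode)
  if (is.null(lengthCounts) && n < 0L) stop("n must be nonnegative")
  withSeed(seed, {
    lens <- if (!is.null(lengthCounts)) {
      rep(as.integer(names(lengthCounts)), times = lengthCounts)
    } else if (n > 0L) sampleLengths(n, lengthDist) else integer(0)
    if (length(lens) == 0L) return(character(0))
    if (mode == "iid") {
      letters <- sample(AA_ALPHABET, sum(lens), replace = TRUE,
                        prob = background@frequencies)
      ends <- cumsum(lens)
      starts <- ends - lens + 1L
      vapply(seq_along(lens), function(i)
        paste(letters[starts[i]:ends[i]], collapse = ""), character(1L))
    } else {
      if (length(background@pool) == 0L)
        stop("substring mode requires a proteome pool")
      w <- Biostrings::width(background@pool)
      if (max(w) < max(lens))
        stop("requested decoy length ", max(lens),
             " exceeds the longest pool sequence (", max(w), ")")
      vapply(lens, function(L) {
        ok <- which(w >= L)
        s <- ok[sample.int(length(ok), 1L)]
        start <- sample.int(w[s] - L + 1L, 1L)
        substr(as.character(background@pool[s]), start, start + L - 1L)
      }, character(1L))
    }
  })
}
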