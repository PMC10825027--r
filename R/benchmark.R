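# Decoy spike-in benchmarking: evaluation-set assembly, fractional rank
# statistics, binding-core weighting, motif-information correction of log
# ranks, AUPRC / PPV, and percentile bootstrap confidence intervals.

#' Assemble a spike-in evaluation set
#'
#' Mixes `n` verified binder peptides with `round(n * (1 - f) / f)` decoys so
#' the verified peptides make up fraction `f` of the final set (1% by
#' default).  With `matchLengths = TRUE` the decoy length histogram is forced
#' to the verified length histogram (scaled to the decoy count by largest
#' remainders), the rule used for class-II-like sets.
#'
#' @param binders character vector of verified binder peptides.
#' @param decoySource a [BackgroundModel-class].
#' @param spikeFraction verified fraction `f` in (0, 1); default 0.01.
#' @param matchLengths force the decoy length histogram to match the binders.
#' @param mode decoy sampling mode, `"iid"` or `"substring"`.
#' @param allele allele identifier recorded in the dataset.
#' @param seed integer seed.
#' @return An [EvaluationDataset-class].
#' @export
#' @examples
#' ds <- assembleEvaluationSet(sampleDecoys(backgroundModel(), 50, seed = 1),
#'                             backgroundModel(), seed = 2)
#' length(ds)  # 50 binders -> 5000 peptides at the 1% spike fraction
assembleEvaluationSet <- function(binders, decoySource, spikeFraction = 0.01,
                                  matchLengths = FALSE,
                                  mode = c("iid", "substring"),
                                  allele = "unknown", seed = NULL) {
  mode <- match.arg(mode)
  if (length(binders) == 0L) stop("binders must be nonempty")
  if (spikeFraction <= 0 || spikeFraction >= 1)
    stop("spikeFraction must lie in (0, 1)")
  n <- length(binders)
  nDecoys <- roundHalfUp(n * (1 - spikeFraction) / spikeFraction)
  if (matchLengths) {
    h <- table(nchar(binders))
    target <- floor(h / n * nDecoys)
    short <- nDecoys - sum(target)
    if (short > 0L) {  # largest remainders take the leftover counts
      rem <- h / n * nDecoys - target
      add <- order(rem, decreasing = TRUE)[seq_len(short)]
      target[add] <- target[add] + 1L
    }
    counts <- setNames(as.integer(target), names(h))
    decoys <- sampleDecoys(decoySource, lengthCounts = counts, n = nDecoys,
                           mode = mode, seed = seed)
  } else {
    lens <- table(nchar(binders))
    decoys <- sampleDecoys(decoySource, n = nDecoys,
                           lengthDist = setNames(as.numeric(lens), names(lens)),
                           mode = mode, seed = seed)
  }
  pep <- S4Vectors::DataFrame(
    peptide = c(binders, decoys),
    label = c(rep("verified", n), rep("decoy", length(decoys))))
  new("EvaluationDataset", allele = allele, peptides = pep,
      spikeFraction = spikeFraction)
}

#' Score an evaluation set with a predictor
#'
#' Annotates every peptide with its eluted-ligand score and reported 9-mer
#' binding core.  Scoring is per-peptide, so the result does not depend on
#' the input order.
#'
#' @param dataset an [EvaluationDataset-class].
#' @param predictor a [PSSMPredictor-class] or a function predictor (see
#'   [scorePeptides()]).
#' @param mhcSeq the allele's MHC protein sequence.
#' @return The dataset with `score` and `core` columns added.
#' @export
scoreDataset <- function(dataset, predictor, mhcSeq) {
  p <- dataset@peptides
  res <- tryCatch(scorePeptides(predictor, mhcSeq, p$peptide),
                  error = function(e) stop("predictor failed: ",
                                           conditionMessage(e), call. = FALSE))
  if (any(res$score < 0 | res$score > 1))
    stop("predictor returned scores outside [0, 1]")
  p$score <- res$score
  p$core <- res$core
  dataset@peptides <- p
  dataset
}

#' Fractional rank scores
#'
#' Assigns each peptide the fraction of the evaluation set scoring strictly
#' above it: `rank_i = #\{j : EL_j > EL_i\} / N`, so better-scoring peptides
#' get lower ranks and the top peptide gets rank 0.  Ties contribute nothing
#' under the default strict counting; `ties = "midrank"` shares tied
#' positions.  Because the top rank of 0 has no log, log10 ranks floor the
#' raw rank at `1/(2N)`; floored peptides are flagged in the `floored`
#' column.
#'
#' @param dataset a scored [EvaluationDataset-class].
#' @param ties `"strict"` (default) or `"midrank"`.
#' @return The dataset with `rank`, `logRank` and `floored` columns added.
#' @export
fractionalRanks <- function(dataset, ties = c("strict", "midrank")) {
  ties <- match.arg(ties)
  p <- dataset@peptides
  if (is.null(p$score)) stop("dataset must be scored first")
  N <- nrow(p)
  method <- if (ties == "strict") "max" else "average"
  above <- N - rank(p$score, ties.method = method)
  p$rank <- above / N
  floorAt <- 1 / (2 * N)
  p$floored <- p$rank < floorAt
  p$logRank <- log10(pmax(p$rank, floorAt))
  dataset@peptides <- p
  dataset
}

#' Binding-core weights
#'
#' Verified peptides sharing a reported binding core are down-weighted so
#' that each distinct core carries total weight 1 (longer class-II-like
#' peptides often repeat one core with different flanks).  Decoys keep
#' weight 1.  The weights enter all downstream weighted statistics: medians,
#' the correction regression, PR counts and PPV.
#'
#' @param dataset a scored [EvaluationDataset-class] with cores assigned.
#' @return The dataset with a `weight` column added.
#' @export
coreWeights <- function(dataset) {
  p <- dataset@peptides
  if (is.null(p$core)) stop("cores must be assigned (score the dataset first)")
  w <- rep(1, nrow(p))
  ver <- p$label == "verified"
  if (any(ver)) {
    mult <- table(p$core[ver])
    w[ver] <- 1 / as.numeric(mult[p$core[ver]])
  }
  p$weight <- w
  dataset@peptides <- p
  dataset
}

#' Estimate a binding-motif PFM from verified cores
#'
#' Position frequency matrix over the 9-mer cores of the verified peptides,
#' with a pseudocount added per amino acid per column before normalization.
#' Core weights, when present, enter the counts.
#'
#' @param dataset an [EvaluationDataset-class] with cores (or a character
#'   vector of 9-mer cores).
#' @param pseudocount added to each cell before normalization (default 1).
#' @param background background frequencies `q` stored with the motif.
#' @return A [MotifPFM-class].
#' @export
estimateMotif <- function(dataset, pseudocount = 1,
                          background = humanProteomeFrequencies()) {
  if (is(dataset, "EvaluationDataset")) {
    p <- dataset@peptides
    if (is.null(p$core)) stop("cores must be assigned first")
    ver <- p$label == "verified"
    cores <- p$core[ver]
    w <- if (!is.null(p$weight)) p$weight[ver] else rep(1, sum(ver))
  } else {
    cores <- dataset
    w <- rep(1, length(cores))
  }
  if (length(cores) == 0L) stop("no verified cores to estimate a motif from")
  L <- unique(nchar(cores))
  if (length(L) != 1L) stop("cores must share one length")
  m <- matrix(pseudocount, nrow = 20L, ncol = L,
              dimnames = list(AA_ALPHABET, NULL))
  idx <- peptideIntMatrix(cores)
  for (j in seq_len(L)) {
    tw <- tapply(w, factor(idx[, j], levels = 1:20), sum)
    tw[is.na(tw)] <- 0
    m[, j] <- m[, j] + tw
  }
  m <- sweep(m, 2L, colSums(m), "/")
  q <- background[AA_ALPHABET]; names(q) <- AA_ALPHABET
  new("MotifPFM", matrix = m, pseudocount = pseudocount, background = q / sum(q))
}

#' Motif information content
#'
#' Kullback-Leibler divergence of the motif from the background, summed over
#' core positions: `I = sum_i sum_a p_{a,i} log2(p_{a,i} / q_a)` in bits.
#' High information means a selective, easy-to-predict motif.
#'
#' @param pfm a [MotifPFM-class].
#' @return Information in bits (nonnegative for proper distributions).
#' @export
motifInformation <- function(pfm) {
  q <- pfm@background
  if (any(q <= 0)) stop("background frequencies must be strictly positive")
  p <- pfm@matrix
  sum(p * log2(p / q))
}

#' Fit the motif-information rank correction
#'
#' Ordinary least squares of verified-peptide log10 ranks against their
#' allele's motif information, fitted on the pooled per-peptide records with
#' core weights as regression weights (`perAlleleMedians = TRUE` fits the
#' per-allele weighted medians instead).  The correction factor
#' `C_allele = alpha + beta * I_allele - mu` subtracts the fitted information
#' trend while the grand-mean term `mu` keeps corrected log ranks on the
#' original scale: the weighted mean over the fitted pool is unchanged and a
#' refit on corrected values has slope 0.
#'
#' @param datasets named list of scored, ranked (and ideally core-weighted)
#'   [EvaluationDataset-class] objects; names are allele identifiers.
#' @param information named numeric vector of per-allele motif information in
#'   bits (e.g. from [motifInformation()]); must cover all datasets and vary
#'   across alleles.
#' @param perAlleleMedians fit allele medians instead of pooled peptides.
#' @return An [InformationCorrection-class].
#' @export
fitInformationCorrection <- function(datasets, information,
                                     perAlleleMedians = FALSE) {
  if (length(datasets) < 3L) stop("need at least 3 alleles to fit")
  alleles <- names(datasets)
  if (is.null(alleles) || !all(alleles %in% names(information)))
    stop("datasets must be named by alleles present in `information`")
  pool <- do.call(rbind, lapply(alleles, function(a) {
    p <- datasets[[a]]@peptides
    if (is.null(p$logRank)) stop("dataset ", a, " has no ranks")
    ver <- p$label == "verified"
    data.frame(allele = a, logRank = p$logRank[ver],
               w = if (!is.null(p$weight)) p$weight[ver] else rep(1, sum(ver)),
               I = information[[a]])
  }))
  if (perAlleleMedians) {
    med <- vapply(split(pool, pool$allele), function(d)
      weightedMedian(d$logRank, d$w), numeric(1L))
    pool <- data.frame(allele = names(med), logRank = med, w = 1,
                       I = information[names(med)])
  }
  if (var(pool$I) == 0)
    stop("degenerate regression: motif information is constant across alleles")
  fit <- lm(logRank ~ I, data = pool, weights = w)
  alpha <- unname(coef(fit)[1L]); beta <- unname(coef(fit)[2L])
  mu <- weighted.mean(pool$logRank, pool$w)
  info <- information[alleles]
  new("InformationCorrection", alpha = alpha, beta = beta, mu = mu,
      information = info, correction = alpha + beta * info - mu)
}

#' Apply a rank correction to a dataset
#'
#' Subtracts the allele's correction factor from every peptide's log10 rank
#' and exponentiates back to the rank scale (clamped to \[0, 1\]) for
#' cutoff-based metrics such as [ppv()].
#'
#' @param dataset a ranked [EvaluationDataset-class].
#' @param correction an [InformationCorrection-class]; the dataset's allele
#'   must be among its alleles unless `information` supplies its motif
#'   information directly.
#' @param information optional motif information (bits) for an allele not in
#'   the fitted pool.
#' @return The dataset with `correctedLogRank` and `correctedRank` columns.
#' @export
applyCorrection <- function(dataset, correction, information = NULL) {
  p <- dataset@peptides
  if (is.null(p$logRank)) stop("dataset must be ranked first")
  a <- dataset@allele
  C <- if (a %in% names(correction@correction)) {
    correction@correction[[a]]
  } else if (!is.null(information)) {
    correction@alpha + correction@beta * information - correction@mu
  } else stop("allele ", a, " not in the correction; supply `information`")
  p$correctedLogRank <- p$logRank - C
  p$correctedRank <- pmin(1, pmax(0, 10^p$correctedLogRank))
  dataset@peptides <- p
  dataset
}

# Pick the rank column metrics run on: corrected if present, else raw.
.metricRanks <- function(p) {
  if (!is.null(p$correctedRank)) p$correctedRank
  else if (!is.null(p$rank)) p$rank
  else stop("dataset must be ranked first")
}

#' Area under the precision-recall curve
#'
#' Verified peptides are positives, decoys negatives; peptides are called
#' positive when their (corrected) rank falls below a sweeping cutoff.  All
#' distinct rank values are used as cutoffs (tied ranks are grouped at one
#' threshold), core weights enter the verified counts, and the area is the
#' step-wise sum of precision times recall increments.
#'
#' @param dataset a ranked (and optionally corrected / core-weighted)
#'   [EvaluationDataset-class].
#' @return AUPRC in \[0, 1\].
#' @export
auprc <- function(dataset) {
  p <- dataset@peptides
  r <- .metricRanks(p)
  ver <- p$label == "verified"
  if (!any(ver)) stop("no verified peptides")
  w <- if (!is.null(p$weight)) p$weight else rep(1, nrow(p))
  o <- order(r)  # best (lowest rank) first
  r <- r[o]; ver <- ver[o]; w <- w[o]
  tp <- cumsum(ifelse(ver, w, 0))
  fp <- cumsum(ifelse(ver, 0, 1))  # decoys weigh 1
  last <- c(r[-1L] != r[-length(r)], TRUE)  # group tied ranks
  tp <- tp[last]; fp <- fp[last]
  totalTP <- tp[length(tp)]
  prec <- tp / (tp + fp)
  rec <- tp / totalTP
  sum(diff(c(0, rec)) * prec)
}

#' Positive predictive value at a rank cutoff
#'
#' Weighted fraction of verified peptides whose (corrected) rank is below the
#' cutoff (0.01 by default, matching the spike fraction).
#'
#' @param dataset a ranked [EvaluationDataset-class].
#' @param cutoff rank cutoff (default 0.01).
#' @return PPV in \[0, 1\].
#' @export
ppv <- function(dataset, cutoff = 0.01) {
  p <- dataset@peptides
  r <- .metricRanks(p)
  ver <- p$label == "verified"
  w <- if (!is.null(p$weight)) p$weight else rep(1, nrow(p))
  sum(w[ver & r < cutoff]) / sum(w[ver])
}

#' Per-allele benchmark metrics
#'
#' AUPRC, PPV, the weighted median corrected log rank, and the confusion
#' counts at the reference cutoff.
#'
#' @param dataset a ranked, corrected [EvaluationDataset-class].
#' @param cutoff rank cutoff for PPV and the confusion counts.
#' @return One-row data.frame: `allele`, `auprc`, `ppv`,
#'   `medianCorrectedLogRank`, `TP`, `FP`, `TN`, `FN`.
#' @export
benchmarkMetrics <- function(dataset, cutoff = 0.01) {
  p <- dataset@peptides
  r <- .metricRanks(p)
  lr <- if (!is.null(p$correctedLogRank)) p$correctedLogRank else p$logRank
  ver <- p$label == "verified"
  w <- if (!is.null(p$weight)) p$weight else rep(1, nrow(p))
  pos <- r < cutoff
  data.frame(allele = dataset@allele,
             auprc = auprc(dataset), ppv = ppv(dataset, cutoff),
             medianCorrectedLogRank = weightedMedian(lr[ver], w[ver]),
             TP = sum(w[ver & pos]), FP = sum(!ver & pos),
             TN = sum(!ver & !pos), FN = sum(w[ver & !pos]),
             stringsAsFactors = FALSE)
}

#' Percentile bootstrap CI for a difference of medians
#'
#' Each replicate resamples both groups with replacement to their own sizes
#' and records `median(a*) - median(b*)`; the 0.025 and 0.975 empirical
#' quantiles over replicates form the 95% interval.
#'
#' @param groupA,groupB numeric vectors.
#' @param nReps bootstrap replicates (default 10000).
#' @param seed integer seed.
#' @param conf confidence level (default 0.95).
#' @return Named numeric `c(low, high)`.
#' @export
bootstrapMedianDiffCI <- function(groupA, groupB, nReps = 10000L,
                                  seed = NULL, conf = 0.95) {
  if (length(groupA) == 0L || length(groupB) == 0L)
    stop("both groups must be nonempty")
  if (nReps < 100L) stop("use at least 100 bootstrap replicates")
  withSeed(seed, {
    nA <- length(groupA); nB <- length(groupB)
    mA <- matrix(sample(groupA, nReps * nA, replace = TRUE), nrow = nReps)
    mB <- matrix(sample(groupB, nReps * nB, replace = TRUE), nrow = nReps)
    diffs <- apply(mA, 1L, median) - apply(mB, 1L, median)
    a <- (1 - conf) / 2
    setNames(quantile(diffs, c(a, 1 - a), names = FALSE), c("low", "high"))
  })
}
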