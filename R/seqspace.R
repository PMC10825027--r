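# HLA sequence-space mapping: alignment gap filling, PAM100 similarity ->
# normalized distance, motif Jensen-Shannon divergence, classical MDS, and
# nearest-training-allele statistics.

#' The bundled PAM100 substitution matrix
#'
#' The standard 20 x 20 PAM100 log-odds amino-acid substitution matrix
#' (half-bit scale), as a symmetric integer matrix with one-letter dimnames.
#'
#' @return 20 x 20 numeric matrix.
#' @export
pam100Matrix <- function() {
  path <- system.file("extdata", "PAM100.tsv", package = "mhcbench")
  m <- as.matrix(read.delim(path, row.names = 1L, check.names = FALSE))
  stopifnot(identical(rownames(m), colnames(m)))
  m
}

#' Fill alignment gaps with the column consensus
#'
#' Replaces every gap character by the most frequent amino acid in its
#' alignment column (ties broken alphabetically).  With
#' `terminalOnly = TRUE`, only gaps in a sequence's leading or trailing gap
#' run are filled — the stricter reading when large gaps occur only at the
#' alignment ends — and any interior gap left over is an error.
#'
#' @param alignment [Biostrings::AAStringSet] of equal-width aligned
#'   sequences (gap character `-`), or a named character vector.
#' @param terminalOnly fill only terminal gap runs.
#' @return Gap-free [Biostrings::AAStringSet].
#' @export
fillAlignmentGaps <- function(alignment, terminalOnly = FALSE) {
  seqs <- as.character(alignment)
  if (length(unique(nchar(seqs))) > 1L) stop("alignment rows differ in length")
  chars <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  isGap <- chars == "-"
  if (!any(isGap)) return(Biostrings::AAStringSet(setNames(seqs, names(seqs))))
  fillable <- isGap
  if (terminalOnly) {
    for (i in seq_len(nrow(chars))) {
      run <- rle(isGap[i, ])
      keep <- rep(FALSE, ncol(chars))
      if (run$values[1L]) keep[seq_len(run$lengths[1L])] <- TRUE
      nr <- length(run$values)
      if (run$values[nr])
        keep[(ncol(chars) - run$lengths[nr] + 1L):ncol(chars)] <- TRUE
      fillable[i, ] <- isGap[i, ] & keep
    }
    if (any(isGap & !fillable))
      stop("interior gaps remain under terminalOnly = TRUE")
  }
  for (j in which(apply(fillable, 2L, any))) {
    col <- chars[, j]
    res <- col[col != "-"]
    if (length(res) == 0L) stop("alignment column ", j, " is all gaps")
    counts <- table(res)
    # which.max on a table returns the first maximum; names are sorted
    # alphabetically, so ties break alphabetically.
    consensus <- names(counts)[which.max(counts)]
    chars[fillable[, j], j] <- consensus
  }
  out <- apply(chars, 1L, paste, collapse = "")
  Biostrings::AAStringSet(setNames(out, names(seqs)))
}

#' PAM100 sequence distance matrix
#'
#' Similarity between two equal-length gap-free sequences is the sum of
#' substitution-matrix values over aligned positions,
#' `S(a, b) = sum_i M[a_i, b_i]`.  Raw distance is maximum similarity minus
#' similarity: under the default `"pairwise"` convention the maximum is
#' `max(S(a,a), S(b,b))` per pair (a pseudo-metric with zero diagonal);
#' under `"global"` it is the single largest similarity over all ordered
#' pairs including self-pairs.  The matrix is then divided by its largest
#' entry so the maximum distance is exactly 1; the divisor is recorded.
#'
#' @param sequences [Biostrings::AAStringSet] or named character vector of
#'   equal-length gap-free sequences.
#' @param substitutionMatrix symmetric substitution matrix (default the
#'   bundled PAM100).
#' @param convention `"pairwise"` (default) or `"global"`.
#' @return An [AlleleDistanceMatrix-class].
#' @export
pamDistanceMatrix <- function(sequences, substitutionMatrix = pam100Matrix(),
                              convention = c("pairwise", "global")) {
  convention <- match.arg(convention)
  seqs <- as.character(sequences)
  ids <- names(seqs)
  if (is.null(ids)) ids <- as.character(seq_along(seqs))
  if (length(unique(nchar(seqs))) > 1L) stop("sequences differ in length")
  n <- length(seqs)
  chars <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  idx <- matrix(match(chars, rownames(substitutionMatrix)), nrow = n)
  if (anyNA(idx)) {
    bad <- which(is.na(idx), arr.ind = TRUE)[1L, ]
    stop("unknown amino-acid letter ", sQuote(chars[bad[1L], bad[2L]]),
         " in sequence ", sQuote(ids[bad[1L]]), " at position ", bad[2L])
  }
  S <- matrix(0, n, n, dimnames = list(ids, ids))
  for (a in seq_len(n)) for (b in a:n) {
    s <- sum(substitutionMatrix[cbind(idx[a, ], idx[b, ])])
    S[a, b] <- s; S[b, a] <- s
  }
  if (convention == "pairwise") {
    self <- diag(S)
    smax <- outer(self, self, pmax)
    d <- smax - S
  } else {
    d <- max(S) - S
  }
  normalizer <- max(d)
  if (normalizer > 0) d <- d / normalizer else normalizer <- 1
  new("AlleleDistanceMatrix", distances = d, normalizer = normalizer,
      convention = convention)
}

#' Distance between two binding motifs
#'
#' Summed per-position divergence between two position frequency matrices of
#' equal core length: Jensen-Shannon divergence in bits (default; bounded by
#' 1 bit per position) or symmetric Kullback-Leibler divergence
#' `(KL(A||B) + KL(B||A)) / 2`.  Both are symmetric and zero iff the motifs
#' are identical.
#'
#' @param pfmA,pfmB [MotifPFM-class] objects with equal core length.
#' @param method `"jsd"` (default) or `"symmetric_kl"`.
#' @return Nonnegative distance in bits.
#' @export
motifPairDistance <- function(pfmA, pfmB, method = c("jsd", "symmetric_kl")) {
  method <- match.arg(method)
  a <- pfmA@matrix; b <- pfmB@matrix
  if (ncol(a) != ncol(b)) stop("motif core lengths differ")
  total <- 0
  for (i in seq_len(ncol(a))) {
    p <- a[, i]; q <- b[, i]
    if (method == "jsd") {
      m <- (p + q) / 2
      total <- total + sum(p * log2(p / m)) / 2 + sum(q * log2(q / m)) / 2
    } else {
      total <- total + (sum(p * log2(p / q)) + sum(q * log2(q / p))) / 2
    }
  }
  total
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Embeds a distance matrix into `k` dimensions by double-centering the
#' squared distances and eigendecomposing (via [stats::cmdscale()] with
#' default parameters).  If fewer than `k` positive eigenvalues exist the
#' remaining coordinates are zero-padded with a warning.  Coordinates are
#' determined up to the sign of each axis.
#'
#' @param dm an [AlleleDistanceMatrix-class] or symmetric matrix with zero
#'   diagonal.
#' @param k embedding dimension (default 2).
#' @return An [MDSEmbedding-class].
#' @export
classicalMDS <- function(dm, k = 2L) {
  d <- if (is(dm, "AlleleDistanceMatrix")) dm@distances else as.matrix(dm)
  n <- nrow(d)
  if (k < 1L || k > n - 1L) stop("k must lie in [1, n - 1]")
  fit <- withCallingHandlers(
    cmdscale(d, k = k, eig = TRUE),
    warning = function(w) invokeRestart("muffleWarning"))
  pts <- fit$points
  if (is.null(dim(pts))) pts <- matrix(pts, ncol = 1L)
  if (ncol(pts) < k) {
    warning("only ", ncol(pts), " positive eigenvalues; padding to k = ", k,
            " with zero coordinates")
    pts <- cbind(pts, matrix(0, nrow = n, ncol = k - ncol(pts)))
  }
  pts[is.na(pts)] <- 0
  rownames(pts) <- rownames(d)
  if (n > 0L) pts <- sweep(pts, 2L, colMeans(pts))  # exact centering
  new("MDSEmbedding", points = pts, eig = sort(fit$eig, decreasing = TRUE))
}

#' Distance to the nearest training allele
#'
#' For every allele outside the training set, the minimum distance to any
#' training allele — the "how novel is this allele" statistic.
#'
#' @param dm an [AlleleDistanceMatrix-class].
#' @param trainingAlleles nonempty character vector of allele identifiers
#'   present in the matrix.
#' @param includeTraining also report training alleles (their distance is 0
#'   by self-inclusion).
#' @return Named numeric vector of minima over the queried alleles.
#' @export
nearestTrainingDistance <- function(dm, trainingAlleles,
                                    includeTraining = FALSE) {
  d <- dm@distances
  if (length(trainingAlleles) == 0L) stop("training set is empty")
  miss <- setdiff(trainingAlleles, rownames(d))
  if (length(miss)) stop("unknown training alleles: ",
                         paste(miss, collapse = ", "))
  query <- if (includeTraining) rownames(d)
           else setdiff(rownames(d), trainingAlleles)
  if (length(query) == 0L) return(setNames(numeric(0), character(0)))
  apply(d[query, trainingAlleles, drop = FALSE], 1L, min)
}

#' Correlation between sequence and motif distances
#'
#' Pearson correlation over the shared allele pairs (upper triangle) of a
#' sequence distance matrix and a motif distance matrix — how well sequence
#' proximity predicts motif proximity.
#'
#' @param seqDM,motifDM [AlleleDistanceMatrix-class] objects (or matrices)
#'   over a shared allele set.
#' @return List with `r` (Pearson correlation) and `nPairs`.
#' @export
seqVsMotifCorrelation <- function(seqDM, motifDM) {
  a <- if (is(seqDM, "AlleleDistanceMatrix")) seqDM@distances else as.matrix(seqDM)
  b <- if (is(motifDM, "AlleleDistanceMatrix")) motifDM@distances else as.matrix(motifDM)
  shared <- intersect(rownames(a), rownames(b))
  if (length(shared) < 3L) stop("need at least 3 shared alleles")
  a <- a[shared, shared]; b <- b[shared, shared]
  ut <- upper.tri(a)
  if (sum(ut) < 3L) stop("need at least 3 allele pairs")
  list(r = cor(a[ut], b[ut]), nPairs = sum(ut))
}

#' Write an embedding to CSV
#'
#' Columns: allele, one column per dimension, and each retained axis's share
#' of the positive eigenvalue mass.
#'
#' @param embedding an [MDSEmbedding-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeEmbedding <- function(embedding, path) {
  pts <- embedding@points
  pos <- sum(pmax(embedding@eig, 0))
  share <- if (pos > 0) pmax(embedding@eig[seq_len(ncol(pts))], 0) / pos
           else rep(0, ncol(pts))
  df <- data.frame(allele = rownames(pts), pts, check.names = FALSE)
  names(df)[-1L] <- paste0("dim", seq_len(ncol(pts)))
  for (j in seq_len(ncol(pts)))
    df[[paste0("eigShare", j)]] <- share[j]
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a distance matrix to TSV
#'
#' @param dm an [AlleleDistanceMatrix-class].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeDistanceMatrix <- function(dm, path) {
  m <- dm@distances
  df <- data.frame(allele = rownames(m), m, check.names = FALSE)
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
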