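# Population coverage of a training-allele set: the fraction of individuals
# in each population carrying at least one allele the predictor has never
# seen, under Hardy-Weinberg random pairing of two independent allele draws.

#' Read an allele-frequency table from CSV
#'
#' Expects columns `population`, `allele`, `frequency` (NMDP-style long
#' format).  Frequencies are validated to \[0, 1\], duplicate
#' (population, allele) rows and per-population sums above 1 are rejected.
#'
#' @param path CSV file path.
#' @param locus locus label to attach.
#' @return An [AlleleFrequencyTable-class].
#' @export
readFrequencyTable <- function(path, locus) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("population", "allele", "frequency")
  if (!all(need %in% names(df)))
    stop("frequency CSV must have columns: ", paste(need, collapse = ", "))
  if (!is.numeric(df$frequency) || anyNA(df$frequency))
    stop("malformed frequency values")
  if (any(df$frequency < 0) || any(df$frequency > 1))
    stop("frequencies must lie in [0, 1]")
  key <- paste(df$population, df$allele, sep = "\r")
  if (anyDuplicated(key)) stop("duplicate (population, allele) rows")
  pops <- sort(unique(df$population))
  alleles <- sort(unique(df$allele))
  m <- matrix(0, nrow = length(pops), ncol = length(alleles),
              dimnames = list(pops, alleles))
  m[cbind(match(df$population, pops), match(df$allele, alleles))] <- df$frequency
  if (any(rowSums(m) > 1 + 1e-6))
    stop("per-population frequencies sum to more than 1")
  new("AlleleFrequencyTable", locus = locus, frequencies = pmin(m, 1))
}

#' Write an allele-frequency table to CSV
#'
#' Long-format companion to [readFrequencyTable()] (zero-frequency cells are
#' omitted).
#'
#' @param table an [AlleleFrequencyTable-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeFrequencyTable <- function(table, path) {
  m <- table@frequencies
  df <- data.frame(population = rep(rownames(m), ncol(m)),
                   allele = rep(colnames(m), each = nrow(m)),
                   frequency = as.vector(m), stringsAsFactors = FALSE)
  df <- df[df$frequency > 0, ]
  df <- df[order(df$population, df$allele), ]
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Fraction of individuals carrying an uncovered allele
#'
#' For each population, sums the frequencies of alleles present in the
#' training set (`coveredMass` p, optionally including the residual mass of
#' alleles unlisted in the table) and reports the Hardy-Weinberg fraction of
#' individuals with at least one uncovered allele, `1 - p^2`.
#'
#' @param table an [AlleleFrequencyTable-class].
#' @param trainingAlleles character vector of allele identifiers with
#'   training data.
#' @param residual `"uncovered"` (default, conservative) or `"covered"`: how
#'   to treat frequency mass of alleles absent from the table.
#' @return A [CoverageReport-class].
#' @export
#' @examples
#' m <- matrix(c(0.5, 0.3, 0.2), 1, dimnames = list("pop1", c("a1","a2","a3")))
#' tab <- new("AlleleFrequencyTable", locus = "A", frequencies = m)
#' uncoveredFraction(tab, "a1")  # covered mass 0.5 -> 1 - 0.25 = 0.75
uncoveredFraction <- function(table, trainingAlleles,
                              residual = c("uncovered", "covered")) {
  residual <- match.arg(residual)
  m <- table@frequencies
  covered <- colnames(m) %in% trainingAlleles
  p <- rowSums(m[, covered, drop = FALSE])
  if (residual == "covered") p <- p + pmax(0, 1 - rowSums(m))
  p <- pmin(p, 1)
  uncov <- colnames(m)[!covered & colSums(m) > 0]
  new("CoverageReport", locus = table@locus,
      table = data.frame(population = rownames(m), coveredMass = unname(p),
                         uncoveredFraction = unname(1 - p^2),
                         stringsAsFactors = FALSE),
      uncoveredAlleles = uncov, residualTreatment = residual)
}

#' Across-locus union of uncovered fractions
#'
#' Probability of carrying at least one uncovered allele at *any* of several
#' independent loci: `1 - prod(p_l^2)` over the per-locus covered masses.
#' Linkage disequilibrium between loci is ignored.
#'
#' @param reports list of [CoverageReport-class] objects sharing populations.
#' @return data.frame with columns `population`, `uncoveredFraction`.
#' @export
combinedUncoveredFraction <- function(reports) {
  pops <- Reduce(intersect, lapply(reports, function(r) r@table$population))
  if (length(pops) == 0L) stop("no shared populations across loci")
  p2 <- sapply(reports, function(r) {
    t <- r@table
    t$coveredMass[match(pops, t$population)]^2
  })
  if (is.null(dim(p2))) p2 <- matrix(p2, nrow = length(pops))
  data.frame(population = pops,
             uncoveredFraction = 1 - apply(p2, 1L, prod),
             stringsAsFactors = FALSE)
}

#' Cross-locus correlation of uncovered fractions
#'
#' Pearson correlation, over shared populations, of the per-population
#' uncovered fractions between every pair of loci.  A locus with constant
#' fractions has undefined correlations, reported as `NA` (not 0).
#'
#' @param reports named list of [CoverageReport-class] objects (names are
#'   locus labels; unnamed lists use each report's locus slot).
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
locusCorrelations <- function(reports) {
  if (is.null(names(reports)))
    names(reports) <- vapply(reports, function(r) r@locus, character(1L))
  pops <- Reduce(intersect, lapply(reports, function(r) r@table$population))
  if (length(pops) < 3L)
    stop("need at least 3 shared populations, found ", length(pops))
  vecs <- sapply(reports, function(r) {
    t <- r@table
    t$uncoveredFraction[match(pops, t$population)]
  })
  k <- length(reports)
  cm <- matrix(NA_real_, k, k, dimnames = list(names(reports), names(reports)))
  diag(cm) <- 1
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i == j) next
    if (var(vecs[, i]) == 0 || var(vecs[, j]) == 0) next  # stays NA
    cm[i, j] <- cor(vecs[, i], vecs[, j])
  }
  cm
}

#' Write a coverage report to CSV
#'
#' @param report a [CoverageReport-class].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
writeCoverageReport <- function(report, path) {
  df <- report@table
  df$locus <- report@locus
  write.csv(df[c("population", "locus", "coveredMass", "uncoveredFraction")],
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
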