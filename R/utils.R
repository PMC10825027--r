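# Internal helpers shared across modules.

# The 20 standard amino acids, alphabetical by one-letter code.
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Approximate amino-acid composition of the human proteome (Swiss-Prot style
# percentages), normalized to sum exactly to 1.  Used as the default decoy
# background q_a and as the reference distribution for motif information.
.HUMAN_AA_FREQ <- local({
  f <- c(A = 8.25, R = 5.53, N = 4.06, D = 5.45, C = 1.38, Q = 3.93,
         E = 6.72, G = 7.07, H = 2.27, I = 5.91, L = 9.65, K = 5.80,
         M = 2.41, F = 3.86, P = 4.74, S = 6.63, T = 5.35, W = 1.10,
         Y = 2.92, V = 6.86)
  f <- f[AA_ALPHABET]
  f / sum(f)
})

#' Background amino-acid frequencies
#'
#' A human-proteome-like amino-acid frequency vector (alphabetical one-letter
#' order), used as the default background for decoy sampling and motif
#' information.
#'
#' @return Named numeric vector of length 20 summing to 1.
#' @export
#' @examples
#' humanProteomeFrequencies()["L"]  # leucine is the most common residue
humanProteomeFrequencies <- function() .HUMAN_AA_FREQ

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched.  seed = NULL uses the ambient stream.
withSeed <- function(seed, code) {
  if (!is.null(seed)) {
    seed <- as.integer(seed)
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

# Map amino-acid letters to indices 1..20; unknown letters -> NA.
aaIndex <- function(letters) match(letters, AA_ALPHABET)

# Split peptides into an integer matrix (rows = peptides of equal length).
peptideIntMatrix <- function(peptides) {
  stopifnot(length(unique(nchar(peptides))) <= 1L)
  if (length(peptides) == 0L) return(matrix(integer(0), nrow = 0))
  chars <- strsplit(peptides, "", fixed = TRUE)
  m <- matrix(aaIndex(unlist(chars)), nrow = length(peptides), byrow = TRUE)
  if (anyNA(m)) {
    bad <- which(apply(is.na(m), 1L, any))[1L]
    stop("peptide ", sQuote(peptides[bad]), " contains a non-standard amino acid")
  }
  m
}

# Round half away from zero (so 0.5 -> 1), used for decoy counts.
roundHalfUp <- function(x) floor(x + 0.5)

# Weighted median: smallest value whose cumulative weight reaches half the
# total; midpoint of the two straddling values when the split is exact.
weightedMedian <- function(x, w = rep(1, length(x))) {
  stopifnot(length(x) == length(w), all(w >= 0))
  if (length(x) == 0L) return(NA_real_)
  o <- order(x)
  x <- x[o]; w <- w[o]
  cw <- cumsum(w) / sum(w)
  i <- which(cw >= 0.5)[1L]
  if (abs(cw[i] - 0.5) < 1e-12 && i < length(x)) (x[i] + x[i + 1L]) / 2 else x[i]
}

# Draw one Dirichlet vector via normalized gammas.
rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  if (all(g == 0)) g <- rep(1, length(alpha))  # degenerate underflow guard
  g / sum(g)
}

# Sample lengths from a named probability vector (names = lengths).
sampleLengths <- function(n, lengthDist) {
  stopifnot(is.numeric(lengthDist), !is.null(names(lengthDist)),
            all(lengthDist >= 0), sum(lengthDist) > 0)
  lens <- as.integer(names(lengthDist))
  if (anyNA(lens)) stop("length distribution names must be integer lengths")
  lens[sample.int(length(lens), n, replace = TRUE, prob = lengthDist)]
}
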