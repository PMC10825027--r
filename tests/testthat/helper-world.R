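# Shared fixtures and independent oracles, all generated in code.

AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
        "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# A small seeded synthetic world reused across tests.
makeWorld <- function(seed = 1, nAlleles = 6, nClusters = 2, L = 40,
                      pockets = c(3, 8, 13, 18, 23, 28, 33, 36, 39),
                      pocketWeights = rep(1, 9)) {
  catalog <- genAlleleCatalog(nAlleles, nClusters, seqLength = L,
                              mutationRate = 0.05, seed = seed)
  spec <- predictorSpec(pockets, pocketWeights = pocketWeights,
                        seed = seed + 100)
  list(catalog = catalog, spec = spec,
       predictor = buildPredictor(catalog, spec),
       seqs = as.character(alleleSequences(catalog)),
       background = backgroundModel(), pockets = pockets)
}

# O(N^2) fractional-rank oracle: strict pairwise counting per Eq.-style
# definition (ties contribute 0); midrank shares tied positions.
oracleRanks <- function(scores, midrank = FALSE) {
  N <- length(scores)
  vapply(scores, function(s) {
    above <- sum(scores > s)
    if (midrank) above <- above + (sum(scores == s) - 1) / 2
    above / N
  }, numeric(1))
}

# Exhaustive threshold-enumeration AUPRC oracle on (rank, label, weight).
oracleAUPRC <- function(r, verified, w = rep(1, length(r))) {
  ts <- sort(unique(r))
  totalTP <- sum(w[verified])
  prevR <- 0
  area <- 0
  for (t in ts) {
    called <- r <= t
    TP <- sum(w[verified & called])
    FP <- sum(!verified & called)
    P <- TP / (TP + FP)
    R <- TP / totalTP
    area <- area + (R - prevR) * P
    prevR <- R
  }
  area
}

# Term-by-term KL information oracle on a PFM matrix and background q.
oracleInformation <- function(m, q) {
  total <- 0
  for (i in seq_len(ncol(m))) for (a in seq_len(nrow(m)))
    total <- total + m[a, i] * log2(m[a, i] / q[a])
  unname(total)
}

# Per-position Jensen-Shannon divergence oracle (bits).
oracleJSD <- function(a, b) {
  total <- 0
  for (i in seq_len(ncol(a))) {
    m <- (a[, i] + b[, i]) / 2
    for (x in seq_len(nrow(a))) {
      total <- total + a[x, i] * log2(a[x, i] / m[x]) / 2
      total <- total + b[x, i] * log2(b[x, i] / m[x]) / 2
    }
  }
  unname(total)
}

# Position-by-position PAM similarity oracle.
oraclePamSimilarity <- function(s1, s2, M) {
  c1 <- strsplit(s1, "")[[1]]
  c2 <- strsplit(s2, "")[[1]]
  total <- 0
  for (i in seq_along(c1)) total <- total + M[c1[i], c2[i]]
  unname(total)
}

# Random pseudocounted PFM (columns sum to 1, strictly positive).
randomPFM <- function(L = 9, seed = 1) {
  set.seed(seed)
  m <- matrix(rgamma(20 * L, shape = 0.8) + 1e-6, nrow = 20,
              dimnames = list(AA, NULL))
  m <- sweep(m, 2, colSums(m), "/")
  new("MotifPFM", matrix = m, pseudocount = 0.001,
      background = humanProteomeFrequencies())
}

# Build an EvaluationDataset with fully controlled scores (function predictor
# returning them in order).
scoredToyDataset <- function(scores, labels, spike = mean(labels == "verified")) {
  n <- length(scores)
  peps <- vapply(seq_len(n), function(i)
    paste(AA[1 + (i + 0:8) %% 20], collapse = ""), character(1))
  ds <- new("EvaluationDataset", allele = "TOY",
            peptides = S4Vectors::DataFrame(peptide = peps, label = labels),
            spikeFraction = spike)
  scoreDataset(ds, function(mhcSeq, peptides) scores, "X")
}
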