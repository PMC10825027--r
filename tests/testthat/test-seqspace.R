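# Sequence-space mapping: gap filling, PAM100 distances, motif divergence,
# classical MDS, nearest-training statistics.

test_that("gap filling uses the column consensus with alphabetical ties", {
  aln <- c(s1 = "AAC", s2 = "A-C", s3 = "-AC")
  out <- as.character(fillAlignmentGaps(aln))
  expect_equal(unname(out), c("AAC", "AAC", "AAC"))

  # tie A vs C -> alphabetical winner A
  tie <- c(s1 = "A", s2 = "C", s3 = "-")
  expect_equal(unname(as.character(fillAlignmentGaps(tie))[3]), "A")

  # gap-free alignment unchanged
  clean <- c(a = "ACD", b = "ACD")
  expect_equal(unname(as.character(fillAlignmentGaps(clean))),
               unname(clean))

  expect_error(fillAlignmentGaps(c(a = "-A", b = "-C")), "all gaps")
})

test_that("terminal-only mode fills flank runs and rejects interior gaps", {
  aln <- c(s1 = "--ACDEF", s2 = "KKACDEF")
  out <- as.character(fillAlignmentGaps(aln, terminalOnly = TRUE))
  expect_equal(unname(out[1]), "KKACDEF")

  interior <- c(s1 = "AC-DEF", s2 = "ACDDEF")
  expect_error(fillAlignmentGaps(interior, terminalOnly = TRUE), "interior")
  # but the default mode fills it
  expect_equal(unname(as.character(fillAlignmentGaps(interior))[1]), "ACDDEF")
})

test_that("the bundled PAM100 matrix is the canonical symmetric table", {
  M <- pam100Matrix()
  expect_identical(dim(M), c(20L, 20L))
  expect_identical(M, t(M))
  # spot values from the published table
  expect_equal(unname(M["A", "A"]), 4)
  expect_equal(unname(M["W", "W"]), 12)
  expect_equal(unname(M["C", "C"]), 9)
  expect_equal(unname(M["D", "W"]), -9)
})

test_that("PAM distances match a double-loop oracle and the conventions", {
  M <- pam100Matrix()
  set.seed(13)
  seqs <- setNames(vapply(1:4, function(i)
    paste(sample(AA, 30, replace = TRUE), collapse = ""), character(1)),
    paste0("al", 1:4))
  dm <- pamDistanceMatrix(seqs)

  # identical sequence pair: S(s,s) = sum of diagonal entries along s
  sSelf <- oraclePamSimilarity(seqs[1], seqs[1], M)
  expect_equal(sSelf, sum(M[cbind(strsplit(seqs[1], "")[[1]],
                                  strsplit(seqs[1], "")[[1]])]))

  # raw distances from the oracle, then the same normalization
  raw <- matrix(0, 4, 4)
  for (a in 1:4) for (b in 1:4) {
    smax <- max(oraclePamSimilarity(seqs[a], seqs[a], M),
                oraclePamSimilarity(seqs[b], seqs[b], M))
    raw[a, b] <- smax - oraclePamSimilarity(seqs[a], seqs[b], M)
  }
  expect_equal(unname(dm@distances), raw / max(raw), tolerance = 1e-12)

  expect_identical(dm@distances, t(dm@distances))
  expect_equal(unname(diag(dm@distances)), rep(0, 4))
  expect_equal(max(dm@distances), 1)
  expect_equal(dm@normalizer, max(raw))

  # global convention: single max over ordered pairs including self-pairs
  dg <- pamDistanceMatrix(seqs, convention = "global")
  S <- matrix(0, 4, 4)
  for (a in 1:4) for (b in 1:4)
    S[a, b] <- oraclePamSimilarity(seqs[a], seqs[b], M)
  rawG <- max(S) - S
  expect_equal(unname(dg@distances), rawG / max(rawG), tolerance = 1e-12)

  expect_error(pamDistanceMatrix(c(x = "AXA", y = "AAA"),
                                 substitutionMatrix = M), "unknown amino-acid")
})

test_that("motif distances match closed forms and the per-term oracle", {
  pfmA <- randomPFM(seed = 1)
  pfmB <- randomPFM(seed = 2)
  expect_equal(motifPairDistance(pfmA, pfmA), 0, tolerance = 1e-12)
  expect_equal(motifPairDistance(pfmA, pfmA, method = "symmetric_kl"), 0,
               tolerance = 1e-12)

  # near-point masses on different letters at one position -> JSD -> 1 bit
  mk <- function(letter) {
    eps <- 1e-9
    m <- matrix(eps, 20, 1, dimnames = list(AA, NULL))
    m[letter, 1] <- 1 - 19 * eps
    new("MotifPFM", matrix = m, pseudocount = 0,
        background = humanProteomeFrequencies())
  }
  expect_equal(motifPairDistance(mk("A"), mk("C")), 1, tolerance = 1e-6)

  # random pair: value within [0, L] bits and equal to the summation oracle
  d <- motifPairDistance(pfmA, pfmB)
  expect_gte(d, 0); expect_lte(d, 9)
  expect_equal(d, oracleJSD(pfmA@matrix, pfmB@matrix), tolerance = 1e-12)

  # symmetry of both methods
  expect_equal(motifPairDistance(pfmA, pfmB), motifPairDistance(pfmB, pfmA))
  expect_equal(motifPairDistance(pfmA, pfmB, "symmetric_kl"),
               motifPairDistance(pfmB, pfmA, "symmetric_kl"))

  short <- randomPFM(L = 5, seed = 3)
  expect_error(motifPairDistance(pfmA, short), "length")
})

test_that("classical MDS reconstructs Euclidean-realizable distances", {
  # 1-D points {0, 3, 5}
  d <- as.matrix(dist(matrix(c(0, 3, 5), ncol = 1)))
  rownames(d) <- colnames(d) <- c("x", "y", "z")
  emb <- classicalMDS(d, k = 1)
  rec <- as.matrix(dist(emb@points))
  expect_equal(unname(rec), unname(d), tolerance = 1e-9)

  # all-zero matrix -> everything at the origin (zero eigenvalues)
  z <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  expect_warning(embz <- classicalMDS(z, k = 2), "padding")
  expect_equal(unname(embz@points), matrix(0, 3, 2))

  # random 6-point 2-D configuration recovered at k = 2
  set.seed(8)
  pts <- matrix(rnorm(12), ncol = 2)
  d6 <- as.matrix(dist(pts))
  dimnames(d6) <- list(paste0("p", 1:6), paste0("p", 1:6))
  emb6 <- classicalMDS(d6, k = 2)
  expect_equal(unname(as.matrix(dist(emb6@points))), unname(d6),
               tolerance = 1e-9)
  expect_true(all(abs(colMeans(emb6@points)) < 1e-9))
  expect_false(is.unsorted(rev(emb6@eig)))
})

test_that("nearest-training distances are exhaustive minima", {
  set.seed(4)
  m <- matrix(runif(25), 5, 5)
  m <- (m + t(m)) / 2; diag(m) <- 0
  ids <- paste0("a", 1:5)
  dimnames(m) <- list(ids, ids)
  dm <- new("AlleleDistanceMatrix", distances = m / max(m),
            normalizer = max(m), convention = "pairwise")
  training <- c("a1", "a3")
  ntd <- nearestTrainingDistance(dm, training)
  for (q in names(ntd))
    expect_equal(ntd[[q]], min(dm@distances[q, training]))

  # training allele queried anyway: distance 0 to itself
  all_ <- nearestTrainingDistance(dm, training, includeTraining = TRUE)
  expect_equal(unname(all_[training]), c(0, 0))

  # training = all alleles -> empty result
  expect_length(nearestTrainingDistance(dm, ids), 0L)
  expect_error(nearestTrainingDistance(dm, character(0)), "empty")
})

test_that("sequence-vs-motif correlation detects linear and null relations", {
  set.seed(9)
  m <- matrix(runif(36), 6, 6); m <- (m + t(m)) / 2; diag(m) <- 0
  ids <- paste0("a", 1:6); dimnames(m) <- list(ids, ids)
  r1 <- seqVsMotifCorrelation(m, 2 * m)
  expect_equal(r1$r, 1)
  expect_equal(r1$nPairs, 15L)

  # independent random distances: r ~ 0 averaged over seeds
  rs <- sapply(1:10, function(s) {
    set.seed(s)
    a <- matrix(runif(400), 20, 20); a <- (a + t(a)) / 2; diag(a) <- 0
    b <- matrix(runif(400), 20, 20); b <- (b + t(b)) / 2; diag(b) <- 0
    dimnames(a) <- dimnames(b) <- list(paste0("x", 1:20), paste0("x", 1:20))
    seqVsMotifCorrelation(a, b)$r
  })
  expect_lt(abs(mean(rs)), 0.1)
})

test_that("pocket-keyed worlds link sequence proximity to motif proximity", {
  w <- makeWorld(seed = 23, nAlleles = 8, nClusters = 2)
  dm <- pamDistanceMatrix(alleleSequences(w$catalog))
  ids <- names(w$catalog)
  motifs <- lapply(ids, function(a) {
    pwm <- predictorPWM(w$predictor, w$seqs[a])
    m <- apply(pwm, 2, function(col) { e <- exp(col - max(col)); e / sum(e) })
    rownames(m) <- AA
    new("MotifPFM", matrix = m, pseudocount = 0,
        background = humanProteomeFrequencies())
  })
  names(motifs) <- ids
  mdm <- matrix(0, 8, 8, dimnames = list(ids, ids))
  for (a in 1:8) for (b in 1:8) if (b > a) {
    d <- motifPairDistance(motifs[[a]], motifs[[b]])
    mdm[a, b] <- d; mdm[b, a] <- d
  }
  expect_gt(seqVsMotifCorrelation(dm@distances, mdm)$r, 0)

  # within-cluster sequence distances below between-cluster ones
  cl <- alleleClusters(w$catalog)
  d <- dm@distances
  same <- outer(cl, cl, "==") & upper.tri(d)
  diff <- outer(cl, cl, "!=") & upper.tri(d)
  expect_lt(mean(d[same]), mean(d[diff]))
})
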