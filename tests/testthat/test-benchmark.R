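# Spike-in benchmark statistics: set assembly, fractional ranks, core
# weights, motif information, rank correction, AUPRC/PPV, bootstrap CIs.

test_that("evaluation sets contain the requested spike fraction", {
  bg <- backgroundModel()
  binders <- sampleDecoys(bg, 50, seed = 1)
  ds <- assembleEvaluationSet(binders, bg, spikeFraction = 0.01, seed = 2)
  expect_equal(length(ds), 5000L)
  expect_equal(nVerified(ds), 50L)

  ds2 <- assembleEvaluationSet(binders, bg, spikeFraction = 0.01, seed = 2)
  expect_identical(as.data.frame(peptideTable(ds)),
                   as.data.frame(peptideTable(ds2)))

  expect_error(assembleEvaluationSet(character(0), bg), "nonempty")
  expect_error(assembleEvaluationSet(binders, bg, spikeFraction = 1), "spikeFraction")
})

test_that("length matching forces the decoy histogram onto the binder one", {
  bg <- backgroundModel()
  binders <- c(sampleDecoys(bg, 12, lengthDist = c("9" = 1), seed = 3),
               sampleDecoys(bg, 38, lengthDist = c("15" = 1), seed = 4))
  ds <- assembleEvaluationSet(binders, bg, spikeFraction = 0.01,
                              matchLengths = TRUE, seed = 5)
  p <- peptideTable(ds)
  decoyLens <- table(nchar(p$peptide[p$label == "decoy"]))
  expect_identical(as.vector(decoyLens), c(1188L, 3762L))  # 12/50, 38/50 of 4950
  expect_identical(names(decoyLens), c("9", "15"))
})

test_that("fractional ranks match the O(N^2) pairwise-counting oracle", {
  set.seed(42)
  for (case in 1:3) {
    N <- c(100, 500, 37)[case]
    scores <- round(runif(N), c(3, 1, 2)[case])  # coarse rounding makes ties
    labels <- rep(c("verified", "decoy"), length.out = N)
    ds <- fractionalRanks(scoredToyDataset(scores, labels))
    expect_equal(peptideTable(ds)$rank, oracleRanks(scores), tolerance = 1e-12)
    dsm <- fractionalRanks(scoredToyDataset(scores, labels), ties = "midrank")
    expect_equal(peptideTable(dsm)$rank, oracleRanks(scores, midrank = TRUE),
                 tolerance = 1e-12)
  }
})

test_that("rank extremes: top peptide floored for the log, bottom at (N-1)/N", {
  N <- 200
  scores <- seq_len(N) / N
  ds <- fractionalRanks(scoredToyDataset(scores,
                                         rep(c("verified", "decoy"),
                                             length.out = N)))
  p <- peptideTable(ds)
  top <- which.max(scores)
  expect_equal(p$rank[top], 0)
  expect_true(p$floored[top])
  expect_equal(p$logRank[top], log10(1 / (2 * N)))  # log10(1/400) ~ -2.602
  bottom <- which.min(scores)
  expect_equal(p$rank[bottom], (N - 1) / N)
  expect_false(any(p$floored[-top]))

  # injective scores: rank multiset is {0, 1/N, ..., (N-1)/N}
  expect_equal(sort(p$rank), (seq_len(N) - 1) / N)
  expect_equal(mean(p$rank), (N - 1) / (2 * N))
})

test_that("core weights split each shared core equally among verified peptides", {
  scores <- c(0.9, 0.8, 0.7, 0.6, 0.5, 0.2)
  labels <- c(rep("verified", 4), "decoy", "decoy")
  ds <- scoredToyDataset(scores, labels)
  p <- ds@peptides
  p$core <- c("AAAAAAAAA", "AAAAAAAAA", "AAAAAAAAA", "CCCCCCCCC",
              "AAAAAAAAA", "DDDDDDDDD")
  ds@peptides <- p
  ds <- coreWeights(ds)
  w <- peptideTable(ds)$weight
  expect_equal(w, c(1/3, 1/3, 1/3, 1, 1, 1))
  # weighted verified count = number of distinct verified cores
  ver <- peptideTable(ds)$label == "verified"
  expect_equal(sum(w[ver]), 2)

  # all cores unique -> all weights 1
  ds2 <- coreWeights(scoredToyDataset(scores[1:4], labels[1:4]))
  expect_true(all(peptideTable(ds2)$weight == 1))
})

test_that("motif information matches closed forms and the summation oracle", {
  q <- humanProteomeFrequencies()
  # p = q at every position -> 0 bits
  m0 <- matrix(rep(q, 9), ncol = 9, dimnames = list(AA, NULL))
  pfm0 <- new("MotifPFM", matrix = m0, pseudocount = 0, background = q)
  expect_equal(motifInformation(pfm0), 0, tolerance = 1e-12)

  # near-point mass against uniform background ~ log2(20) bits
  uni <- setNames(rep(1 / 20, 20), AA)
  eps <- 1e-12
  p1 <- matrix(eps, nrow = 20, ncol = 1, dimnames = list(AA, NULL))
  p1[1, 1] <- 1 - 19 * eps
  pfm1 <- new("MotifPFM", matrix = p1, pseudocount = 0, background = uni)
  expect_equal(motifInformation(pfm1), log2(20), tolerance = 1e-6)

  # random PFM vs independent double-loop summation
  pfm <- randomPFM(seed = 6)
  expect_equal(motifInformation(pfm),
               oracleInformation(pfm@matrix, pfm@background),
               tolerance = 1e-12)
})

test_that("estimated motifs are proper pseudocounted distributions", {
  cores <- c("AAAAAAAAC", "AAAAAAAAD", "AAAAAAAAC")
  pfm <- estimateMotif(cores, pseudocount = 1)
  expect_equal(colSums(pfm@matrix), rep(1, 9))
  expect_true(all(pfm@matrix > 0))
  # position 1: 3 As + 1 pseudocount each -> A gets (3+1)/23
  expect_equal(unname(pfm@matrix["A", 1]), 4 / 23)
  expect_equal(unname(pfm@matrix["C", 9]), 3 / 23)
})

test_that("information correction removes the trend and preserves the mean", {
  set.seed(99)
  info <- c(A1 = 2, A2 = 5, A3 = 8, A4 = 11)
  datasets <- lapply(names(info), function(a) {
    n <- 40
    logRank <- -2 + 0.1 * info[[a]] + rnorm(n, sd = 0.3)
    ds <- scoredToyDataset(runif(n), rep("verified", n))
    p <- ds@peptides
    p$logRank <- logRank
    p$weight <- runif(n, 0.5, 1)
    ds@peptides <- p
    ds@allele <- a
    ds
  })
  names(datasets) <- names(info)
  corr <- fitInformationCorrection(datasets, info)

  pool <- do.call(rbind, lapply(names(info), function(a) {
    p <- datasets[[a]]@peptides
    data.frame(lr = p$logRank, w = p$weight, I = info[[a]],
               C = corr@correction[[a]])
  }))
  # grand weighted mean unchanged after correction
  expect_equal(weighted.mean(pool$lr - pool$C, pool$w),
               weighted.mean(pool$lr, pool$w), tolerance = 1e-9)
  # refitted slope on corrected values is zero
  refit <- lm(I(lr - C) ~ I, data = pool, weights = w)
  expect_lt(abs(coef(refit)[2]), 1e-9)
  # correction identity C = alpha + beta I - mu
  expect_equal(unname(corr@correction),
               unname(corr@alpha + corr@beta * info - corr@mu))

  # flat log ranks: beta = 0 and the correction is the identity
  flat <- lapply(datasets, function(ds) {
    ds@peptides$logRank <- rep(-1.5, nrow(ds@peptides))
    ds
  })
  corrFlat <- fitInformationCorrection(flat, info)
  expect_equal(corrFlat@beta, 0, tolerance = 1e-12)
  expect_equal(unname(corrFlat@correction), rep(0, 4), tolerance = 1e-9)

  # constant information is degenerate
  expect_error(fitInformationCorrection(datasets,
                                        setNames(rep(3, 4), names(info))),
               "degenerate")
})

test_that("applyCorrection shifts log ranks and exponentiates to rank scale", {
  ds <- fractionalRanks(scoredToyDataset(runif(50, min = 0.01),
                                         rep(c("verified", "decoy"),
                                             length.out = 50)))
  corr <- new("InformationCorrection", alpha = 0.5, beta = 0, mu = 0,
              information = c(TOY = 3), correction = c(TOY = 0.5))
  out <- applyCorrection(ds, corr)
  p <- peptideTable(out)
  expect_equal(p$correctedLogRank, p$logRank - 0.5)
  expect_true(all(p$correctedRank >= 0 & p$correctedRank <= 1))
  expect_equal(p$correctedRank[p$correctedLogRank < 0],
               10^p$correctedLogRank[p$correctedLogRank < 0])
})

test_that("AUPRC matches exhaustive threshold enumeration", {
  # the four-peptide textbook case
  ds <- fractionalRanks(scoredToyDataset(c(0.9, 0.8, 0.7, 0.1),
                                         c("verified", "decoy",
                                           "verified", "decoy")))
  expect_equal(auprc(ds), 5 / 6)
  p <- peptideTable(ds)
  expect_equal(auprc(ds), oracleAUPRC(p$rank, p$label == "verified"))

  # randomized cases incl. ties and weights
  set.seed(7)
  for (i in 1:4) {
    N <- 300
    scores <- round(runif(N), 2)
    labels <- ifelse(runif(N) < 0.2, "verified", "decoy")
    if (!any(labels == "verified")) labels[1] <- "verified"
    ds <- coreWeights(fractionalRanks(scoredToyDataset(scores, labels)))
    p <- peptideTable(ds)
    expect_equal(auprc(ds),
                 oracleAUPRC(p$rank, p$label == "verified", p$weight),
                 tolerance = 1e-9)
  }

  # perfect separation
  dsP <- fractionalRanks(scoredToyDataset(c(runif(5, 0.9, 1), runif(95, 0, 0.5)),
                                          c(rep("verified", 5),
                                            rep("decoy", 95))))
  expect_equal(auprc(dsP), 1)
})

test_that("random scores give AUPRC and PPV near the spike prevalence", {
  vals <- t(sapply(1:10, function(s) {
    set.seed(s)
    N <- 10000
    labels <- c(rep("verified", 100), rep("decoy", N - 100))
    ds <- fractionalRanks(scoredToyDataset(runif(N), labels, spike = 0.01))
    c(auprc(ds), ppv(ds, 0.01))
  }))
  expect_equal(mean(vals[, 1]), 0.01, tolerance = 0.01)
  expect_equal(mean(vals[, 2]), 0.01, tolerance = 0.01)
})

test_that("PPV is exact for perfect predictors and vacuous cutoffs", {
  N <- 10000
  scores <- c(seq(0.51, 1, length.out = 100), seq(0, 0.49, length.out = N - 100))
  labels <- c(rep("verified", 100), rep("decoy", N - 100))
  ds <- fractionalRanks(scoredToyDataset(scores, labels, spike = 0.01))
  expect_equal(ppv(ds, 0.01), 1)  # all verified ranks < 0.01 under strict counting
  expect_equal(ppv(ds, 1.0), 1)   # vacuous cutoff
})

test_that("bootstrap CIs behave on degenerate and null inputs", {
  ci0 <- bootstrapMedianDiffCI(rep(5, 20), rep(5, 20), nReps = 200, seed = 1)
  expect_equal(unname(ci0), c(0, 0))

  set.seed(2)
  x <- rnorm(100)
  ci <- bootstrapMedianDiffCI(x, x, nReps = 2000, seed = 3)
  expect_lte(ci[["low"]], 0)
  expect_gte(ci[["high"]], 0)

  expect_error(bootstrapMedianDiffCI(numeric(0), x), "nonempty")
  expect_error(bootstrapMedianDiffCI(x, x, nReps = 10), "100")
})

test_that("bootstrap CI endpoints converge as replicates double", {
  set.seed(11)
  a <- rnorm(200); b <- rnorm(200, 0.2)
  # Monte-Carlo SE of each endpoint estimated from repeated 2000-rep CIs
  reps <- t(sapply(1:10, function(s)
    bootstrapMedianDiffCI(a, b, nReps = 2000, seed = 100 + s)))
  se <- apply(reps, 2, sd)
  big <- bootstrapMedianDiffCI(a, b, nReps = 4000, seed = 999)
  expect_lt(abs(big[["low"]] - mean(reps[, 1])), 3 * se[1] + 1e-8)
  expect_lt(abs(big[["high"]] - mean(reps[, 2])), 3 * se[2] + 1e-8)
})

test_that("alleles generating their binders separate sharply from decoys", {
  w <- makeWorld(seed = 17, nAlleles = 4, nClusters = 2)
  ids <- names(w$catalog)
  datasets <- list(); info <- numeric(0)
  for (i in seq_along(ids)) {
    binders <- sampleBinders(w$predictor, w$seqs[i], 60, seed = 50 + i)
    ds <- assembleEvaluationSet(binders, w$background, allele = ids[i],
                                seed = 60 + i)
    ds <- coreWeights(fractionalRanks(scoreDataset(ds, w$predictor, w$seqs[i])))
    info[ids[i]] <- motifInformation(estimateMotif(ds))
    datasets[[ids[i]]] <- ds
  }
  corr <- fitInformationCorrection(datasets, info)
  meds <- vapply(datasets, function(ds) {
    p <- peptideTable(applyCorrection(ds, corr))
    ver <- p$label == "verified"
    mhcbench:::weightedMedian(p$correctedLogRank[ver], p$weight[ver])
  }, numeric(1))
  expect_true(all(meds < -1.3))
})
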