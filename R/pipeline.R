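# End-to-end orchestration: synthetic world -> coverage -> benchmark ->
# sequence space -> occlusion, with strict config validation, derived
# per-stage seeds and a reproducibility manifest.

#' Default pipeline configuration
#'
#' All knobs of [runPipeline()] with their defaults.  The single global
#' `seed` fans out to per-stage child seeds as `seed * 100 + stage index`
#' (world = 1, coverage = 2, benchmark = 3, seqspace = 4, occlusion = 5), so
#' any stage can be rerun in isolation.
#'
#' @return Nested named list.
#' @export
defaultPipelineConfig <- function() {
  list(
    seed = 1L,
    outDir = file.path(tempdir(), "mhcbench_run"),
    world = list(
      nAlleles = 12L, nClusters = 3L, seqLength = 60L, mutationRate = 0.05,
      nPopulations = 8L, concentration = 0.5,
      pocketPositions = NULL,        # NULL = spread 9 pockets over the sequence
      nBinders = 100L, lengthDist = c("9" = 1)),
    spikeFraction = 0.01,
    trainingFraction = 0.5,
    bootstrapReps = 2000L,
    occlusionK = 5L,
    writePeptideTables = FALSE,
    stages = list(coverage = TRUE, benchmark = TRUE, seqspace = TRUE,
                  occlusion = TRUE)
  )
}

# Strict merge: every key in `config` must exist in `default` (recursively
# for the nested blocks), so typos fail before any stage runs.
.mergeConfig <- function(default, config, path = "") {
  if (is.null(config)) return(default)
  unknown <- setdiff(names(config), names(default))
  if (length(unknown))
    stop("unknown config key", if (length(unknown) > 1L) "s", ": ",
         paste0(path, unknown, collapse = ", "))
  for (k in names(config)) {
    if (is.list(default[[k]]) && !is.null(names(default[[k]])) &&
        k %in% c("world", "stages")) {
      default[[k]] <- .mergeConfig(default[[k]], config[[k]],
                                   paste0(path, k, "."))
    } else {
      default[[k]] <- config[[k]]
    }
  }
  default
}

.stageSeed <- function(seed, stage) as.integer(seed) * 100L + stage

#' Run the full benchmark pipeline
#'
#' Generates a seeded synthetic world (allele catalog, population
#' frequencies, pocket-keyed predictor, binder sets), then runs population
#' coverage, spike-in benchmarking with motif-information correction,
#' sequence-space mapping, and an occlusion scan of the worst-performing
#' held-out allele.  All tables are written under `outDir` together with a
#' JSON manifest (seed, config, versions, output checksums); identical
#' config and seed reproduce the outputs byte-identically.
#'
#' @param config nested list overriding [defaultPipelineConfig()] entries, or
#'   a path to a YAML file of the same shape.  Unknown keys are rejected.
#' @return The manifest, invisibly (a named list).
#' @export
runPipeline <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- .mergeConfig(defaultPipelineConfig(), config)
  if (is.list(cfg$world$lengthDist))
    cfg$world$lengthDist <- unlist(cfg$world$lengthDist)
  dir.create(cfg$outDir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(cfg$outDir, f)
  written <- character(0)
  note <- function(path) written <<- c(written, path)

  ## stage 1: synthetic world ------------------------------------------------
  w <- cfg$world
  catalog <- genAlleleCatalog(w$nAlleles, w$nClusters, w$seqLength,
                              w$mutationRate, seed = .stageSeed(cfg$seed, 1L))
  freqs <- genPopulationFrequencies(catalog, w$nPopulations, w$concentration,
                                    seed = .stageSeed(cfg$seed, 1L) + 7L)
  pockets <- w$pocketPositions
  if (is.null(pockets))
    pockets <- as.integer(round(seq(5, w$seqLength - 2, length.out = 9)))
  spec <- predictorSpec(pockets, seed = .stageSeed(cfg$seed, 1L) + 13L)
  predictor <- buildPredictor(catalog, spec)
  background <- backgroundModel()
  ids <- names(catalog)
  nTrain <- max(1L, roundHalfUp(length(ids) * cfg$trainingFraction))
  training <- ids[unique(as.integer(round(seq(1, length(ids),
                                              length.out = nTrain))))]
  note(writeCatalogFasta(catalog, out("catalog.fasta")))
  note(writeFrequencyTable(freqs, out("frequencies.csv")))
  note(writePredictorSpec(spec, out("predictor_spec.json")))
  writeLines(training, out("training_alleles.txt")); note(out("training_alleles.txt"))

  results <- list(catalog = catalog, frequencies = freqs,
                  predictor = predictor, training = training)

  ## stage 2: coverage -------------------------------------------------------
  if (isTRUE(cfg$stages$coverage)) {
    report <- uncoveredFraction(freqs, training)
    note(writeCoverageReport(report, out("coverage.csv")))
    results$coverage <- report
  }

  ## stage 3: benchmark ------------------------------------------------------
  if (isTRUE(cfg$stages$benchmark)) {
    seqs <- as.character(alleleSequences(catalog))
    datasets <- list(); info <- numeric(0); motifs <- list()
    bseed <- .stageSeed(cfg$seed, 3L)
    for (i in seq_along(ids)) {
      a <- ids[i]
      binders <- sampleBinders(predictor, seqs[a], w$nBinders,
                               lengthDist = w$lengthDist,
                               background = background, seed = bseed + 2L * i)
      ds <- assembleEvaluationSet(binders, background,
                                  spikeFraction = cfg$spikeFraction,
                                  allele = a, seed = bseed + 2L * i + 1L)
      ds <- scoreDataset(ds, predictor, seqs[a])
      ds <- fractionalRanks(ds)
      ds <- coreWeights(ds)
      motifs[[a]] <- estimateMotif(ds)
      info[a] <- motifInformation(motifs[[a]])
      datasets[[a]] <- ds
    }
    corr <- fitInformationCorrection(datasets, info)
    datasets <- lapply(datasets, applyCorrection, correction = corr)
    metrics <- do.call(rbind, lapply(datasets, benchmarkMetrics))
    metrics$training <- metrics$allele %in% training
    metrics$information <- unname(info[metrics$allele])
    write.csv(metrics, out("benchmark_metrics.csv"), row.names = FALSE,
              quote = FALSE)
    note(out("benchmark_metrics.csv"))
    if (isTRUE(cfg$writePeptideTables)) {
      for (a in ids) {
        p <- as.data.frame(datasets[[a]]@peptides)
        f <- out(sprintf("peptides_%s.tsv", gsub("[*:]", "_", a)))
        write.table(p, f, sep = "\t", row.names = FALSE, quote = FALSE)
        note(f)
      }
    }
    pull <- function(train) unlist(lapply(datasets[if (train) training
                                                   else setdiff(ids, training)],
      function(d) {
        p <- d@peptides
        p$correctedLogRank[p$label == "verified"]
      }))
    ci <- bootstrapMedianDiffCI(pull(TRUE), pull(FALSE),
                                nReps = cfg$bootstrapReps,
                                seed = bseed + 9999L)
    writeLines(sprintf("median_diff_ci_low\t%.6f\nmedian_diff_ci_high\t%.6f",
                       ci[1L], ci[2L]), out("bootstrap_ci.tsv"))
    note(out("bootstrap_ci.tsv"))
    results$benchmark <- list(datasets = datasets, metrics = metrics,
                              correction = corr, motifs = motifs,
                              information = info, medianDiffCI = ci)
  }

  ## stage 4: sequence space -------------------------------------------------
  if (isTRUE(cfg$stages$seqspace)) {
    dm <- pamDistanceMatrix(alleleSequences(catalog))
    emb <- classicalMDS(dm, k = 2L)
    ntd <- nearestTrainingDistance(dm, training)
    note(writeDistanceMatrix(dm, out("seq_distances.tsv")))
    note(writeEmbedding(emb, out("mds.csv")))
    write.table(data.frame(allele = names(ntd), distance = unname(ntd)),
                out("nearest_training.tsv"), sep = "\t", row.names = FALSE,
                quote = FALSE)
    note(out("nearest_training.tsv"))
    results$seqspace <- list(distances = dm, embedding = emb,
                             nearestTraining = ntd)
    if (!is.null(results$benchmark)) {
      motifs <- results$benchmark$motifs
      mdm <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
      for (a in seq_along(ids)) for (b in seq_along(ids)) {
        if (b > a) {
          d <- motifPairDistance(motifs[[ids[a]]], motifs[[ids[b]]])
          mdm[a, b] <- d; mdm[b, a] <- d
        }
      }
      rho <- seqVsMotifCorrelation(dm@distances, mdm)
      writeLines(sprintf("seq_vs_motif_pearson_r\t%.6f\nn_pairs\t%d",
                         rho$r, rho$nPairs), out("seq_vs_motif.tsv"))
      note(out("seq_vs_motif.tsv"))
      results$seqspace$seqVsMotif <- rho
    }
  }

  ## stage 5: occlusion ------------------------------------------------------
  if (isTRUE(cfg$stages$occlusion) && !is.null(results$benchmark)) {
    held <- setdiff(ids, training)
    metrics <- results$benchmark$metrics
    cand <- if (length(held)) held else ids
    worst <- cand[which.max(metrics$medianCorrectedLogRank[
      match(cand, metrics$allele)])]
    seqs <- as.character(alleleSequences(catalog))
    pool <- results$benchmark$datasets[[worst]]@peptides
    verified <- pool$peptide[pool$label == "verified"]
    profile <- substitutionScan(predictor, seqs[worst], verified,
                                k = cfg$occlusionK, allele = worst)
    rec <- recoveryMetrics(rankResidues(profile), spec$pocketPositions)
    note(writeSensitivityProfile(profile, out("sensitivity_profile.tsv")))
    writeLines(sprintf("allele\t%s\nprecision_at_m\t%.4f\nworst_pocket_rank\t%d",
                       worst, rec$precisionAtM, rec$worstPocketRank),
               out("pocket_recovery.tsv"))
    note(out("pocket_recovery.tsv"))
    results$occlusion <- list(profile = profile, recovery = rec,
                              allele = worst)
  }

  ## manifest -----------------------------------------------------------------
  manifest <- list(
    package = "mhcbench",
    version = as.character(packageVersion("mhcbench")),
    rVersion = as.character(getRversion()),
    seed = cfg$seed,
    stageSeeds = setNames(as.list(.stageSeed(cfg$seed, 1:5)),
                          c("world", "coverage", "benchmark", "seqspace",
                            "occlusion")),
    config = cfg[setdiff(names(cfg), "outDir")],
    outputs = as.list(setNames(unname(md5sum(written)), basename(written))))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  results$manifest <- manifest
  invisible(results)
}
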