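#' Default end-to-end run configuration
#'
#' A single JSON-serializable document driving [runDemo()] and the
#' command-line stages. Unknown keys are rejected on validation so typos
#' fail loudly. One global seed fans out into per-stage streams via
#' [deriveSeed()], so stages can be re-run independently yet
#' reproducibly.
#'
#' @param ... overrides of the default fields (partial nested lists are
#'   merged).
#' @return a validated named list.
#' @export
runConfig <- function(...) {
  default <- list(
    seed = 1L,
    simulator = list(nSequences = 1500L, seqLength = 40L, rounds = 1L,
                     motifFraction = 0.1, noiseCv = 0.1,
                     beadsPerSequence = 10L,
                     concentrations = c(256, 64, 16, 4),
                     coverage = 50),
    clustering = list(maxEdit = 5L, cosineDistanceMax = 0.9,
                      allPairsCap = 1e5L),
    labeling = list(coverageFraction = 0.2),
    model = list(formulation = "superbin", preset = "paper",
                 epochs = 15L, nFolds = 5L, testFold = 0L),
    walk = list(rounds = 5L, mutantsPerRound = 1000L,
                maxSubstitutions = 4L, parentCap = 100L,
                selectedPerRound = 5L, nSeeds = 3L,
                screenCandidates = 20000L, screenTopFraction = 2.5e-4),
    truncation = list(lengths = c(15L, 19L, 23L, 27L, 31L, 35L, 39L),
                      rankMode = "max_median"),
    enrichment = list(kRange = 4:8, alpha = 0.05),
    output = NULL)
  override <- list(...)
  merge <- function(base, upd, path = "") {
    for (nm in names(upd)) {
      if (!nm %in% names(base)) {
        stop("unknown config key: ", paste0(path, nm))
      }
      if (is.list(base[[nm]]) && is.list(upd[[nm]])) {
        base[[nm]] <- merge(base[[nm]], upd[[nm]],
                            paste0(path, nm, "$"))
      } else {
        base[[nm]] <- upd[[nm]]
      }
    }
    base
  }
  merge(default, override)
}

#' Read / write a run configuration as JSON
#' @param path JSON file path.
#' @param config a [runConfig()] list.
#' @return `readRunConfig` returns the validated config.
#' @export
writeRunConfig <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname writeRunConfig
#' @export
readRunConfig <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(runConfig, raw)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("[stage: ", name, "] ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full screening-to-design loop on simulated data
#'
#' Executes every stage of the methodology against the built-in
#' simulator: simulate a particle-display screen, cluster the observed
#' sequences, label them across the stringency ladder, train an affinity
#' model on the cluster-split training folds, screen random seeds with
#' the model, run guided and random walks, evaluate the walked
#' candidates against the ground-truth oracle, scan the best candidate
#' for core truncations, and screen positives for enriched k-mers. The
#' returned report is fully determined by `config$seed`.
#'
#' @param config a [runConfig()].
#' @param verbose print stage progress.
#' @return a report list: `concordance`, per-formulation held-out
#'   `auc`, `walks` (per-level candidate fractions for guided and
#'   random), `topCores`, `motif` and provenance.
#' @export
runDemo <- function(config = runConfig(), verbose = FALSE) {
  seed <- config$seed
  say <- function(...) if (verbose) message(...)

  say("simulate")
  sim <- .stage("simulate", {
    simCfg <- config$simulator
    simulateExperiment(
      nSequences = simCfg$nSequences, seqLength = simCfg$seqLength,
      ladder = stringencyLadder(concentrations = simCfg$concentrations,
                                coverage = simCfg$coverage),
      rounds = simCfg$rounds, motifFraction = simCfg$motifFraction,
      noiseCv = simCfg$noiseCv,
      beadsPerSequence = simCfg$beadsPerSequence,
      seed = deriveSeed(seed, "sim"))
  })
  poolSet <- pools(sim)
  oracle <- simOracle(sim)

  say("cluster")
  clusters <- .stage("cluster", {
    clusterWithProjection(poolSet,
                          allPairsCap = config$clustering$allPairsCap,
                          maxEdit = config$clustering$maxEdit,
                          cosineDistanceMax =
                            config$clustering$cosineDistanceMax)
  })

  say("label")
  labels <- .stage("label", {
    labelPools(poolSet,
               coverageFraction = config$labeling$coverageFraction)
  })
  conc <- .stage("label", concordance(labels))

  say("split + train")
  split <- splitFolds(clusters, nFolds = config$model$nFolds,
                      testFold = config$model$testFold,
                      seed = deriveSeed(seed, "split"))
  formulations <- config$model$formulation
  if (identical(formulations, "all")) {
    formulations <- c("counts", "binned", "superbin")
  }
  models <- list()
  auc <- list()
  for (f in formulations) {
    fit <- .stage(paste0("train_", f), {
      tr <- if (f == "counts") {
        makeTrainingTargets(poolSet = poolSet[split$train, ],
                            formulation = "counts")
      } else {
        trainLabels <- new("StringencyLabels",
                           labels = labelMatrix(labels)[
                             intersect(split$train, sequences(labels)), ,
                             drop = FALSE],
                           concentrations = concentrations(labels))
        makeTrainingTargets(labels = trainLabels, formulation = f)
      }
      trainModel(tr, modelPreset(f, epochs = config$model$epochs),
                 seed = deriveSeed(seed, paste0("train_", f)))
    })
    models[[f]] <- fit
    testSeqs <- intersect(split$test, sequences(labels))
    auc[[f]] <- .stage(paste0("evaluate_", f), {
      testLabels <- new("StringencyLabels",
                        labels = labelMatrix(labels)[testSeqs, ,
                                                     drop = FALSE],
                        concentrations = concentrations(labels))
      stringencyAuc(affinityScore(fit, testSeqs), testLabels, 1L)
    })
  }
  model <- models[[length(models)]]
  scorer <- function(s) affinityScore(model, s)

  say("seed screen + walks")
  wcfg <- walkConfig(rounds = config$walk$rounds,
                     mutantsPerRound = config$walk$mutantsPerRound,
                     maxSubstitutions = config$walk$maxSubstitutions,
                     parentCap = config$walk$parentCap,
                     selectedPerRound = config$walk$selectedPerRound)
  seeds <- .stage("screen", {
    mlSeeds <- screenRandomSeeds(
      scorer, nCandidates = config$walk$screenCandidates,
      topFraction = config$walk$screenTopFraction,
      seqLength = config$simulator$seqLength,
      seed = deriveSeed(seed, "screen"))
    head(unname(mlSeeds), config$walk$nSeeds)
  })
  walks <- .stage("walk", {
    guided <- lapply(seq_along(seeds), function(i) {
      guidedWalk(seeds[i], scorer, wcfg, provenance = "ml_screened",
                 seed = deriveSeed(seed, paste0("walk", i)))
    })
    random <- lapply(seq_along(seeds), function(i) {
      randomWalk(seeds[i], wcfg, provenance = "ml_screened",
                 seed = deriveSeed(seed, paste0("rwalk", i)))
    })
    ladder <- stringencyLadder(
      concentrations = config$simulator$concentrations,
      coverage = config$simulator$coverage)
    list(guided = evaluateWalks(guided, oracle, ladder),
         random = evaluateWalks(random, oracle, ladder),
         guidedTrajectories = guided, randomTrajectories = random)
  })

  say("truncate")
  topCores <- .stage("truncate", {
    bestCand <- walks$guidedTrajectories[[1L]]
    tab <- walkTable(bestCand)
    best <- tab$mutant[tab$round > 0][which.max(tab$score[tab$round > 0])]
    scans <- scanCores(best, scorer,
                       lengths = config$truncation$lengths)
    head(rankCores(scans, config$truncation$rankMode), 10L)
  })

  say("enrich")
  motif <- .stage("enrich", {
    lab <- labelMatrix(labels)
    posSeqs <- rownames(lab)[lab[, 1L] == "positive"]
    negSeqs <- rownames(lab)[lab[, 1L] == "negative"]
    if (length(posSeqs) < 5L || length(negSeqs) < 5L) {
      list(consensus = NA_character_, table = NULL)
    } else {
      tab <- differentialKmerEnrichment(posSeqs, negSeqs,
                                        kRange = config$enrichment$kRange,
                                        alpha = config$enrichment$alpha)
      list(consensus = attr(tab, "consensus"),
           consensusK = attr(tab, "consensusK"),
           table = head(tab, 20L))
    }
  })

  report <- list(
    seed = seed,
    library = list(nSequences = nrow(trueLibrary(sim)),
                   nPools = ncol(poolSet)),
    nClusters = length(representatives(clusters)),
    concordance = as.list(conc),
    auc = auc,
    walks = list(guided = walks$guided, random = walks$random),
    topCores = topCores,
    motif = motif[c("consensus", "consensusK")])
  if (!is.null(config$output)) {
    dir.create(config$output, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report, file.path(config$output, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
  }
  report
}
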