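#' Build training targets for a model formulation
#'
#' Converts screening data into the target arrays of the three output
#' formulations:
#' * `counts` — per-pool normalized sequencing fractions (one output per
#'   pool); nothing is masked. The "positive" set used for batch
#'   upsampling is sequences whose summed raw count across all pools
#'   reaches `positiveCountThreshold`.
#' * `binned` — per-stringency ternary labels encoded positive = 1,
#'   negative = 0; ambiguous entries are masked out of the squared-error
#'   loss. Positives are sequences positive at any stringency.
#' * `superbin` — the scalar 0..2s SuperBin level; excluded (conflicting
#'   or fully ambiguous) sequences are dropped from the training set.
#'   Positives are sequences with level > 0.
#'
#' @param poolSet a [PoolSet] (required for `counts`).
#' @param labels a [StringencyLabels] (required for `binned` and
#'   `superbin`).
#' @param formulation `"counts"`, `"binned"` or `"superbin"`.
#' @param positiveCountThreshold summed-raw-count threshold over the
#'   positive pools defining positives for the Counts formulation
#'   (upsampling only). Default: 20% of the mean expected bead coverage,
#'   the same reliable-detection rule the ternary labels use.
#' @return list with `sequences`, `targets` (matrix), `mask` (logical
#'   matrix, TRUE = contributes to the loss), `positive` (logical) and
#'   `schema` (formulation, output names, designated score columns).
#' @export
makeTrainingTargets <- function(poolSet = NULL, labels = NULL,
                                formulation = c("counts", "binned",
                                                "superbin"),
                                positiveCountThreshold = NULL) {
  formulation <- match.arg(formulation)
  if (formulation == "counts") {
    stopifnot(!is.null(poolSet))
    mat <- poolCounts(poolSet)
    targets <- normalizeCounts(poolSet)
    info <- poolInfo(poolSet)
    posCols <- rownames(info)[info$polarity == "positive"]
    if (is.null(positiveCountThreshold)) {
      positiveCountThreshold <- 0.2 * mean(info$expectedCoverage)
    }
    positive <- rowSums(mat[, posCols, drop = FALSE]) >=
      positiveCountThreshold
    finalRound <- max(info$round)
    # a score pool must be populated enough to define a ranking: at least
    # 1% of sequences (and >= 5) with non-zero counts
    populated <- colSums(mat > 0) >= max(5, 0.01 * nrow(mat))
    posPools <- info[info$round == finalRound &
                       info$polarity == "positive" &
                       populated[rownames(info)], , drop = FALSE]
    if (nrow(posPools) == 0L) {
      stop("no populated final-round positive pool to score against")
    }
    designated <- rownames(posPools)[order(posPools$concentration)]
    designated <- head(designated, 2L) # two highest-stringency pools
    list(sequences = rownames(mat), targets = targets,
         mask = matrix(TRUE, nrow(targets), ncol(targets)),
         positive = unname(positive),
         schema = list(formulation = "counts",
                       outputs = colnames(targets),
                       scoreColumns = designated))
  } else if (formulation == "binned") {
    stopifnot(!is.null(labels))
    lab <- labelMatrix(labels)
    targets <- matrix(NA_real_, nrow(lab), ncol(lab),
                      dimnames = dimnames(lab))
    targets[lab == "positive"] <- 1
    targets[lab == "negative"] <- 0
    mask <- !is.na(targets)
    targets[!mask] <- 0
    list(sequences = rownames(lab), targets = targets, mask = mask,
         positive = unname(rowSums(lab == "positive") > 0),
         schema = list(formulation = "binned",
                       outputs = colnames(lab),
                       concentrations = concentrations(labels)))
  } else {
    stopifnot(!is.null(labels))
    lvl <- superBin(labels)
    keep <- !is.na(lvl)
    targets <- matrix(as.numeric(lvl[keep]), ncol = 1L,
                      dimnames = list(names(lvl)[keep], "superbin"))
    list(sequences = rownames(targets), targets = targets,
         mask = matrix(TRUE, nrow(targets), 1L),
         positive = unname(targets[, 1L] > 0),
         schema = list(formulation = "superbin", outputs = "superbin",
                       concentrations = concentrations(labels)))
  }
}

#' Train a sequence-to-affinity model
#'
#' Mini-batch gradient descent (momentum SGD or Adam per the spec) on the
#' masked squared-error loss. When positive sequences exist, each batch
#' is topped up so positives make at least `upsampleFloor` (default 10%)
#' of it. Targets are standardized per output for optimization;
#' predictions are mapped back to the original units. Training is fully
#' deterministic given `seed`.
#'
#' @param targets a target list from [makeTrainingTargets()].
#' @param spec a [ModelSpec] (e.g. [modelPreset()]).
#' @param seed training seed (weights, shuffling, upsampling, dropout).
#' @param maxGradNorm global gradient-norm clip (default 5; `Inf`
#'   disables). Stabilizes momentum SGD under heavy-tailed standardized
#'   count targets.
#' @param verbose print per-epoch loss.
#' @return a [TrainedAffinityModel].
#' @export
trainModel <- function(targets, spec = modelPreset(targets$schema$formulation),
                       seed = 1L, maxGradNorm = 5, verbose = FALSE) {
  X <- encodeSequences(targets$sequences)
  Tmat <- targets$targets
  mask <- targets$mask
  positive <- targets$positive
  n <- nrow(X)
  stopifnot(nrow(Tmat) == n)

  center <- numeric(ncol(Tmat))
  scale <- numeric(ncol(Tmat))
  for (j in seq_len(ncol(Tmat))) {
    v <- Tmat[mask[, j], j]
    center[j] <- if (length(v)) mean(v) else 0
    s <- if (length(v) > 1L) stats::sd(v) else 0
    scale[j] <- if (is.na(s) || s < 1e-12) 1 else s
  }
  Tstd <- sweep(sweep(Tmat, 2L, center, "-"), 2L, scale, "/")
  Tstd[!mask] <- 0

  net <- buildNetwork(spec, ncol(Tmat), inputDim = ncol(X), seed = seed)
  refs <- .paramRefs(net)
  vel <- lapply(refs, function(r) .getParam(net, r) * 0)
  adamM <- vel
  adamV <- vel
  adamT <- 0

  nPosNeeded <- ceiling(spec@upsampleFloor * spec@batchSize)
  posIdx <- which(positive)
  if (length(posIdx) == 0L && spec@upsampleFloor > 0) {
    warning("no positive sequences; training proceeds without upsampling")
  }

  set.seed(deriveSeed(seed, "train"))
  history <- numeric(spec@epochs)
  for (ep in seq_len(spec@epochs)) {
    ord <- sample.int(n)
    epochLoss <- 0
    nBatches <- 0L
    for (start in seq(1L, n, by = spec@batchSize)) {
      idx <- ord[start:min(start + spec@batchSize - 1L, n)]
      idx <- .upsampleBatch(idx, positive, posIdx, nPosNeeded)
      Xb <- X[idx, , drop = FALSE]
      Tb <- Tstd[idx, , drop = FALSE]
      Mb <- mask[idx, , drop = FALSE]
      dropMask <- NULL
      if (spec@dropout > 0 && length(net$dense)) {
        dropMask <- lapply(net$dense, function(ly) {
          matrix(rbinom(length(idx) * length(ly$b), 1L,
                        1 - spec@dropout) / (1 - spec@dropout),
                 nrow = length(idx))
        })
      }
      fwd <- nnForward(net, Xb, keepCache = TRUE, dropMask = dropMask)
      err <- (fwd$Y - Tb) * Mb
      nEff <- max(1L, sum(Mb))
      loss <- sum(err^2) / nEff
      dY <- 2 * err / nEff
      grads <- .nnBackward(net, Xb, fwd, dY, dropMask = dropMask)
      # global-norm gradient clipping keeps momentum SGD stable under the
      # heavy-tailed standardized count targets
      gnorm <- sqrt(sum(vapply(refs, function(r) {
        sum(.getGrad(grads, r)^2)
      }, numeric(1))))
      if (is.finite(maxGradNorm) && gnorm > maxGradNorm) {
        shrink <- maxGradNorm / gnorm
        for (k in seq_along(refs)) {
          grads <- .setGrad(grads, refs[[k]],
                            .getGrad(grads, refs[[k]]) * shrink)
        }
      }
      if (spec@optimizer == "sgd") {
        for (k in seq_along(refs)) {
          g <- .getGrad(grads, refs[[k]])
          vel[[k]] <- spec@momentum * vel[[k]] - spec@learningRate * g
          net <- .setParam(net, refs[[k]], .getParam(net, refs[[k]]) +
                             vel[[k]])
        }
      } else {
        adamT <- adamT + 1
        b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
        for (k in seq_along(refs)) {
          g <- .getGrad(grads, refs[[k]])
          adamM[[k]] <- b1 * adamM[[k]] + (1 - b1) * g
          adamV[[k]] <- b2 * adamV[[k]] + (1 - b2) * g^2
          mhat <- adamM[[k]] / (1 - b1^adamT)
          vhat <- adamV[[k]] / (1 - b2^adamT)
          net <- .setParam(net, refs[[k]], .getParam(net, refs[[k]]) -
                             spec@learningRate * mhat / (sqrt(vhat) + eps))
        }
      }
      epochLoss <- epochLoss + loss
      nBatches <- nBatches + 1L
    }
    history[ep] <- epochLoss / nBatches
    if (verbose) message("epoch ", ep, " loss ", signif(history[ep], 4))
  }

  new("TrainedAffinityModel",
      weights = net, spec = spec,
      formulation = targets$schema$formulation,
      targetSchema = targets$schema,
      targetCenter = center, targetScale = scale,
      history = data.frame(epoch = seq_len(spec@epochs), loss = history))
}

#' Predict model outputs for sequences
#'
#' @param model a [TrainedAffinityModel].
#' @param sequences character vector of length-40 sequences.
#' @return numeric matrix (sequences x outputs) on the original target
#'   scale, with an attribute `latent` (numeric vector) for
#'   latent-affinity models.
#' @export
predictModel <- function(model, sequences) {
  X <- encodeSequences(sequences)
  fwd <- nnForward(model@weights, X)
  Y <- sweep(sweep(fwd$Y, 2L, model@targetScale, "*"), 2L,
             model@targetCenter, "+")
  colnames(Y) <- model@targetSchema$outputs
  rownames(Y) <- NULL
  if (!is.null(fwd$latent)) attr(Y, "latent") <- fwd$latent
  Y
}

#' @rdname affinityScore
#' @export
setMethod("affinityScore", "TrainedAffinityModel",
          function(object, sequences) {
  Y <- predictModel(object, sequences)
  switch(object@formulation,
    counts = {
      cols <- object@targetSchema$scoreColumns
      rowSums(Y[, cols, drop = FALSE])
    },
    binned = {
      # stringency-rank weights: strongest level weighted highest
      w <- seq_len(ncol(Y))
      as.vector(Y %*% w)
    },
    superbin = as.vector(Y[, 1L]))
})

#' Latent affinity of a latent-head model
#'
#' @param model a [TrainedAffinityModel] with the latent-affinity head.
#' @param sequences character vector of sequences.
#' @return numeric vector: the scalar latent affinity per sequence.
#' @export
latentAffinity <- function(model, sequences) {
  if (model@spec@head != "latent_affinity") {
    stop("model was not built with the latent_affinity head")
  }
  lat <- attr(predictModel(model, sequences), "latent")
  as.vector(lat)
}

setMethod("show", "TrainedAffinityModel", function(object) {
  cat("TrainedAffinityModel (", object@formulation, " formulation)\n",
      sep = "")
  cat("  outputs:", length(object@targetSchema$outputs),
      "| head:", object@spec@head,
      "| optimizer:", object@spec@optimizer, "\n")
  cat("  lr:", object@spec@learningRate, " momentum:",
      object@spec@momentum, " batch:", object@spec@batchSize, "\n")
  if (nrow(object@history)) {
    cat("  final training loss:",
        signif(object@history$loss[nrow(object@history)], 4), "after",
        nrow(object@history), "epochs\n")
  }
})

#' Save / load a trained model checkpoint
#'
#' A single portable JSON file embedding the model specification,
#' target schema, standardization constants and all weights.
#'
#' @param model a [TrainedAffinityModel].
#' @param path file path.
#' @return `loadModel` returns the restored [TrainedAffinityModel];
#'   `saveModel` returns `path` invisibly.
#' @export
saveModel <- function(model, path) {
  spec <- model@spec
  specList <- lapply(setNames(slotNames(spec), slotNames(spec)),
                     function(s) slot(spec, s))
  net <- model@weights
  flat <- function(ly) list(W = as.vector(ly$W), dimW = dim(ly$W),
                            b = as.vector(ly$b))
  payload <- list(
    formulation = model@formulation,
    spec = specList,
    targetSchema = model@targetSchema,
    targetCenter = model@targetCenter,
    targetScale = model@targetScale,
    nOutputs = net$nOutputs,
    inputDim = net$inputDim,
    conv = lapply(net$conv, flat),
    dense = lapply(net$dense, flat),
    head = if (spec@head == "latent_affinity") {
      list(wA = as.vector(net$head$wA), bA = net$head$bA,
           m = net$head$m, bOut = net$head$bOut)
    } else {
      flat(net$head)
    },
    history = model@history)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = FALSE)
  num <- function(x) as.numeric(unlist(x, use.names = FALSE))
  specIn <- p$spec
  spec <- modelSpec(
    convFilters = as.integer(num(specIn$convFilters)),
    convWidth = as.integer(num(specIn$convWidth)),
    hidden = as.integer(num(specIn$hidden)),
    activation = specIn$activation, dropout = num(specIn$dropout),
    head = specIn$head, optimizer = specIn$optimizer,
    learningRate = num(specIn$learningRate),
    momentum = num(specIn$momentum),
    batchSize = as.integer(num(specIn$batchSize)),
    epochs = as.integer(num(specIn$epochs)),
    upsampleFloor = num(specIn$upsampleFloor))
  net <- buildNetwork(spec, as.integer(num(p$nOutputs)),
                      inputDim = as.integer(num(p$inputDim)), seed = 1L)
  unflat <- function(ly) list(W = matrix(num(ly$W), num(ly$dimW)[1],
                                         num(ly$dimW)[2]),
                              b = num(ly$b))
  for (ci in seq_along(net$conv)) {
    got <- unflat(p$conv[[ci]])
    net$conv[[ci]]$W <- got$W
    net$conv[[ci]]$b <- got$b
  }
  for (di in seq_along(net$dense)) {
    net$dense[[di]][c("W", "b")] <- unflat(p$dense[[di]])
  }
  if (spec@head == "latent_affinity") {
    net$head <- list(wA = matrix(num(p$head$wA), ncol = 1),
                     bA = num(p$head$bA), m = num(p$head$m),
                     bOut = num(p$head$bOut))
  } else {
    net$head <- unflat(p$head)
  }
  schema <- lapply(p$targetSchema, function(x) {
    unlist(x, use.names = FALSE)
  })
  new("TrainedAffinityModel", weights = net, spec = spec,
      formulation = p$formulation, targetSchema = schema,
      targetCenter = num(p$targetCenter),
      targetScale = num(p$targetScale),
      history = data.frame(
        epoch = as.integer(num(lapply(p$history, `[[`, "epoch"))),
        loss = num(lapply(p$history, `[[`, "loss"))))
}

#' Seeded random hyperparameter search
#'
#' A simple stand-in for a managed black-box tuning service: draws
#' `nConfigs` random specifications (learning rate, momentum, hidden
#' sizes, dropout), trains each on the training targets, scores it on
#' held-out data with [aucTopFraction()], and returns the configurations
#' ranked by that metric.
#'
#' @param trainTargets,testTargets target lists from
#'   [makeTrainingTargets()] for disjoint cluster folds.
#' @param reference numeric reference values for the test sequences
#'   (e.g. summed high-stringency counts).
#' @param nConfigs number of random configurations (default 8).
#' @param topFraction relevance fraction for the ranking metric.
#' @param epochs training epochs per configuration.
#' @param seed search seed.
#' @return data.frame of configurations with their AUCs, best first;
#'   attribute `models` holds the trained models in the same order.
#' @export
hyperparameterSearch <- function(trainTargets, testTargets, reference,
                                 nConfigs = 8L, topFraction = 0.01,
                                 epochs = 10L, seed = 1L) {
  set.seed(deriveSeed(seed, "search"))
  draws <- data.frame(
    learningRate = 10^runif(nConfigs, -3.2, -1.8),
    momentum = runif(nConfigs, 0.4, 0.95),
    hidden1 = sample(c(32L, 64L, 128L), nConfigs, replace = TRUE),
    hidden2 = sample(c(0L, 16L, 32L), nConfigs, replace = TRUE),
    dropout = sample(c(0, 0.1, 0.2), nConfigs, replace = TRUE))
  base <- modelPreset(trainTargets$schema$formulation, epochs = epochs)
  models <- vector("list", nConfigs)
  auc <- numeric(nConfigs)
  for (i in seq_len(nConfigs)) {
    hid <- draws$hidden1[i]
    if (draws$hidden2[i] > 0L) hid <- c(hid, draws$hidden2[i])
    spec <- base
    spec@learningRate <- draws$learningRate[i]
    spec@momentum <- draws$momentum[i]
    spec@hidden <- hid
    spec@dropout <- draws$dropout[i]
    models[[i]] <- trainModel(trainTargets, spec,
                              seed = deriveSeed(seed, paste0("cfg", i)))
    scores <- affinityScore(models[[i]], testTargets$sequences)
    auc[i] <- aucTopFraction(scores, reference, topFraction)
  }
  draws$auc <- auc
  ord <- order(-auc)
  out <- draws[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "models") <- models[ord]
  out
}
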