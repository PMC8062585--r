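test_that("network shapes hold with convolutions and both heads", {
  set.seed(2)
  X <- encodeSequences(randomSequences(7))
  spec <- modelSpec(convFilters = c(8L, 6L, 4L), hidden = 12L)
  net <- buildNetwork(spec, nOutputs = 3L, seed = 1)
  Y <- aptML:::nnForward(net, X)$Y
  expect_equal(dim(Y), c(7L, 3L))
  lat <- buildNetwork(modelSpec(head = "latent_affinity"), 4L, seed = 1)
  out <- aptML:::nnForward(lat, X)
  expect_equal(dim(out$Y), c(7L, 4L))
  expect_length(out$latent, 7L)
  # zeroed multipliers kill every output regardless of input
  lat$head$m <- rep(0, 4)
  lat$head$bOut <- rep(0, 4)
  expect_equal(aptML:::nnForward(lat, X)$Y, matrix(0, 7, 4))
  expect_error(buildNetwork(modelSpec(head = "latent_affinity"), 1L),
               "scalar target")
})

test_that("backpropagation matches numerical gradients", {
  set.seed(4)
  X <- encodeSequences(randomSequences(5))
  for (spec in list(modelSpec(hidden = c(10L, 6L)),
                    modelSpec(convFilters = 5L, hidden = 8L),
                    modelSpec(hidden = 8L, head = "latent_affinity"))) {
    nOut <- 3L
    Tm <- matrix(rnorm(5 * nOut), 5, nOut)
    M <- matrix(TRUE, 5, nOut); M[1, 2] <- FALSE
    net <- buildNetwork(spec, nOut, seed = 9)
    fwd <- aptML:::nnForward(net, X, keepCache = TRUE)
    dY <- 2 * (fwd$Y - Tm) * M / sum(M)
    grads <- aptML:::.nnBackward(net, X, fwd, dY)
    lossOf <- function(nn) {
      sum(((aptML:::nnForward(nn, X)$Y - Tm) * M)^2) / sum(M)
    }
    for (ref in aptML:::.paramRefs(net)) {
      P <- aptML:::.getParam(net, ref)
      G <- aptML:::.getGrad(grads, ref)
      ii <- sample.int(length(P), 1)
      eps <- 1e-6
      Pp <- P; Pp[ii] <- Pp[ii] + eps
      Pm <- P; Pm[ii] <- Pm[ii] - eps
      num <- (lossOf(aptML:::.setParam(net, ref, Pp)) -
                lossOf(aptML:::.setParam(net, ref, Pm))) / (2 * eps)
      expect_lt(abs(num - G[ii]), 1e-5 * max(1, abs(num)))
    }
  }
})

test_that("training targets encode each formulation's contract", {
  ex <- smallSim()
  ps <- pools(ex)
  lab <- suppressWarnings(labelPools(ps))
  # binned: all-negative row is all zeros and fully unmasked
  tb <- makeTrainingTargets(labels = lab, formulation = "binned")
  allNeg <- rowSums(labelMatrix(lab) == "negative") == ncol(labelMatrix(lab))
  expect_true(all(tb$targets[allNeg, ] == 0))
  expect_true(all(tb$mask[allNeg, ]))
  amb <- labelMatrix(lab) == "ambiguous"
  expect_true(all(!tb$mask[amb]))
  # superbin: excluded sequences are absent from the training set
  lvl <- superBin(lab)
  tsb <- makeTrainingTargets(labels = lab, formulation = "superbin")
  expect_setequal(tsb$sequences, names(lvl)[!is.na(lvl)])
  expect_equal(unname(tsb$targets[, 1]),
               unname(lvl[tsb$sequences]))
  # counts: per-sequence target sum equals its total normalized mass
  tc <- suppressWarnings(makeTrainingTargets(poolSet = ps,
                                             formulation = "counts"))
  frac <- suppressWarnings(normalizeCounts(ps))
  expect_equal(unname(rowSums(tc$targets)), unname(rowSums(frac)))
  expect_length(tc$schema$scoreColumns, 2L)
})

test_that("batch upsampling tops positives up to the floor", {
  set.seed(8)
  positive <- rep(c(TRUE, FALSE), c(20, 980))
  posIdx <- which(positive)
  fracs <- vapply(1:200, function(i) {
    idx <- aptML:::.upsampleBatch(sample.int(1000, 64), positive, posIdx,
                                  nPosNeeded = 7L)
    mean(positive[idx])
  }, numeric(1))
  expect_true(all(fracs >= 7 / 64))
  # absent positives: batch unchanged
  idx <- sort(sample.int(1000, 64))
  expect_identical(aptML:::.upsampleBatch(idx, rep(FALSE, 1000),
                                          integer(0), 7L), idx)
})

test_that("training reduces the loss and is seed-reproducible", {
  ex <- smallSim()
  lab <- suppressWarnings(labelPools(pools(ex)))
  tr <- makeTrainingTargets(labels = lab, formulation = "binned")
  m1 <- trainModel(tr, modelPreset("binned", epochs = 8), seed = 42)
  m2 <- trainModel(tr, modelPreset("binned", epochs = 8), seed = 42)
  expect_lt(m1@history$loss[8], m1@history$loss[1])
  expect_identical(m1@history$loss, m2@history$loss)
  expect_identical(predictModel(m1, tr$sequences[1:5]),
                   predictModel(m2, tr$sequences[1:5]))
})

test_that("shuffled labels yield chance-level held-out discrimination", {
  ex <- smallSim()
  lab <- suppressWarnings(labelPools(pools(ex)))
  labm <- labelMatrix(lab)
  set.seed(13)
  shuffled <- labm[sample.int(nrow(labm)), , drop = FALSE]
  rownames(shuffled) <- rownames(labm)
  slab <- makeLabels(shuffled, concentrations(lab))
  half <- seq_len(nrow(labm) %/% 2)
  trLab <- makeLabels(shuffled[half, , drop = FALSE],
                      concentrations(lab))
  teLab <- makeLabels(labm[-half, , drop = FALSE], concentrations(lab))
  tr <- makeTrainingTargets(labels = trLab, formulation = "binned")
  m <- suppressWarnings(trainModel(tr, modelPreset("binned", epochs = 8),
                                   seed = 3))
  auc <- stringencyAuc(affinityScore(m, sequences(teLab)), teLab, 1L)
  expect_gt(auc, 0.35)
  expect_lt(auc, 0.65)
})

test_that("affinity scores reduce outputs per formulation", {
  ex <- smallSim()
  lab <- suppressWarnings(labelPools(pools(ex)))
  tsb <- makeTrainingTargets(labels = lab, formulation = "superbin")
  msb <- trainModel(tsb, modelPreset("superbin", epochs = 3), seed = 1)
  seqs <- tsb$sequences[1:10]
  expect_equal(affinityScore(msb, seqs),
               unname(predictModel(msb, seqs)[, 1]))
  # counts: score is the sum of the designated pool outputs
  tc <- suppressWarnings(makeTrainingTargets(poolSet = pools(ex),
                                             formulation = "counts"))
  mc <- suppressWarnings(trainModel(tc, modelPreset("counts", epochs = 3),
                                    seed = 1))
  Y <- predictModel(mc, seqs)
  expect_equal(affinityScore(mc, seqs),
               unname(rowSums(Y[, tc$schema$scoreColumns])))
  expect_length(latentAffinity(mc, seqs), 10L)
})

test_that("checkpoints round-trip exactly through JSON", {
  ex <- smallSim()
  lab <- suppressWarnings(labelPools(pools(ex)))
  tr <- makeTrainingTargets(labels = lab, formulation = "binned")
  m <- trainModel(tr, modelPreset("binned", epochs = 3), seed = 5)
  path <- tempfile(fileext = ".json")
  saveModel(m, path)
  m2 <- loadModel(path)
  seqs <- tr$sequences[1:8]
  expect_equal(predictModel(m2, seqs), predictModel(m, seqs),
               tolerance = 1e-12)
  expect_equal(m2@spec@learningRate, m@spec@learningRate)
})

test_that("rank AUC agrees with brute-force pairwise counting and pROC", {
  # 10-element fixture: relevant items ranked 1st and 3rd -> 15/16
  scores <- 10:1
  positive <- c(TRUE, FALSE, TRUE, rep(FALSE, 7))
  expect_equal(rankAuc(scores, positive), 15 / 16)
  expect_equal(bruteAuc(scores, positive), 15 / 16)
  set.seed(9)
  s <- rnorm(60)
  p <- rbinom(60, 1, 0.3) == 1
  expect_equal(rankAuc(s, p), bruteAuc(s, p))
  expect_equal(rankAuc(s, p),
               as.numeric(pROC::auc(pROC::roc(p, s, quiet = TRUE,
                                              direction = "<"))))
  expect_error(rankAuc(s, rep(FALSE, 60)), "undefined")
})

test_that("top-fraction AUC uses non-zero reference values only", {
  ref <- c(10, 9, 8, 7, 6, 5, 4, 3, 2, 1, 0, 0)
  scores <- c(12, 1, 11, seq(8, 2, length.out = 7), 99, 99)
  # zeros (with huge scores) are excluded; top-20% = ref values 10 and 9
  auc <- aucTopFraction(scores, ref, topFraction = 0.2)
  expect_equal(auc, bruteAuc(scores[1:10], c(TRUE, TRUE, rep(FALSE, 8))))
  expect_equal(aucTopFraction(ref, ref, 0.1), 1)
  expect_error(aucTopFraction(scores, ref, 1), "every")
})

test_that("stringency AUC scores concordant positives against the rest", {
  lab <- makeLabels(cbind(c("positive", "positive", "negative",
                            "negative"),
                          c("positive", "negative", "negative",
                            "ambiguous")),
                    concentrations = c(256, 64))
  rownames(lab@labels) <- paste0("s", 1:4)
  scores <- c(4, 3, 2, 1)
  expect_equal(stringencyAuc(scores, lab, 1L), 1)
  # level 2: only s1 is concordantly positive
  expect_equal(stringencyAuc(scores, lab, 2L),
               bruteAuc(scores, c(TRUE, FALSE, FALSE, FALSE)))
  # by concentration
  expect_equal(stringencyAuc(scores, lab, 64), stringencyAuc(scores, lab, 2L))
  allNeg <- makeLabels(matrix("negative", 3, 1,
                              dimnames = list(paste0("s", 1:3), NULL)),
                       concentrations = 64)
  expect_error(stringencyAuc(1:3, allNeg, 1L), "undefined")
})
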