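test_that("count normalization yields per-pool fractions", {
  m <- matrix(c(30L, 70L, 0L, 0L), ncol = 2,
              dimnames = list(c("s1", "s2"), c("p1", "p2")))
  expect_warning(f <- normalizeCounts(m), "zero total")
  expect_equal(f[, "p1"], c(s1 = 0.3, s2 = 0.7))
  expect_equal(unname(f[, "p2"]), c(0, 0))
  set.seed(2)
  m2 <- matrix(rpois(30, 40) + 1L, nrow = 10)
  colnames(m2) <- paste0("p", 1:3); rownames(m2) <- paste0("s", 1:10)
  expect_equal(unname(colSums(normalizeCounts(m2))), rep(1, 3))
  expect_equal(sum(normalizeCounts(m2, per = "experiment")), 1)
})

test_that("ternary labels need coverage and a prevalence margin", {
  seqs <- c("strong", "weak", "background")
  counts <- matrix(c(1373L, 10L, 0L,     # positive pool
                     0L, 10L, 5000L),    # negative pool
                   ncol = 2, dimnames = list(seqs, c("pos", "neg")))
  ps <- makePoolSet(counts, concentration = c(64, 64),
                    polarity = c("positive", "negative"),
                    expectedCoverage = 6865)
  lab <- labelMatrix(labelPools(ps))
  # 1373 reads = 20% of the 6865 expected coverage, none in the negative
  expect_equal(unname(lab["strong", 1]), "positive")
  # present in both pools but far below the coverage floor
  expect_equal(unname(lab["weak", 1]), "ambiguous")
  expect_equal(unname(lab["background", 1]), "negative")
  # 1372 reads: one short of the floor
  counts2 <- counts; counts2["strong", "pos"] <- 1372L
  ps2 <- makePoolSet(counts2, concentration = c(64, 64),
                     polarity = c("positive", "negative"),
                     expectedCoverage = 6865)
  expect_equal(unname(labelMatrix(labelPools(ps2))["strong", 1]),
               "ambiguous")
  # missing paired pool is an error
  expect_error(labelPools(ps[, 1]), "paired")
})

test_that("labels from a deep noiseless screen match the oracle thresholds", {
  lad <- stringencyLadder(coverage = 50)
  ex <- simulateExperiment(nSequences = 250, ladder = lad, noiseCv = 0,
                           seed = 55)
  lab <- suppressWarnings(labelPools(pools(ex)))
  lib <- trueLibrary(ex)
  kd <- stats::setNames(lib$kd, lib$sequence)[sequences(lab)]
  thr <- kdThresholds(lad)
  for (j in seq_along(thr)) {
    expected <- ifelse(kd <= thr[j], "positive", "negative")
    observed <- labelMatrix(lab)[, j]
    agree <- mean(observed == expected)
    expect_gte(agree, 0.99)
  }
})

test_that("identical count tables give identical labels", {
  ps <- pools(smallSim())
  l1 <- suppressWarnings(labelPools(ps))
  l2 <- suppressWarnings(labelPools(ps))
  expect_identical(labelMatrix(l1), labelMatrix(l2))
})

test_that("SuperBin interleaves passes and borderline calls into 0..2s", {
  lab <- makeLabels(rbind(
    allneg = c("negative", "negative", "negative"),
    allpos = c("positive", "positive", "positive"),
    one    = c("positive", "negative", "negative"),
    oneamb = c("positive", "ambiguous", "negative"),
    border = c("ambiguous", "negative", "negative"),
    conflict = c("negative", "positive", "negative"),
    allamb = c("ambiguous", "ambiguous", "ambiguous")),
    concentrations = c(256, 64, 16))
  lvl <- superBin(lab)
  expect_equal(unname(lvl[c("allneg", "allpos", "one", "oneamb",
                            "border")]),
               c(0L, 6L, 2L, 3L, 1L))
  expect_true(is.na(lvl["conflict"]))
  expect_true(is.na(lvl["allamb"]))
})

test_that("SuperBin level never decreases when another stringency passes", {
  states <- c("positive", "negative", "ambiguous")
  grid <- expand.grid(a = states, b = states, c = states,
                      stringsAsFactors = FALSE)
  for (r in seq_len(nrow(grid))) {
    row <- unlist(grid[r, ])
    lab0 <- makeLabels(matrix(row, nrow = 1,
                              dimnames = list("s", NULL)),
                       concentrations = c(256, 64, 16))
    # upgrade the first non-positive level to positive
    up <- row
    i <- which(up != "positive")[1]
    if (is.na(i)) next
    up[i] <- "positive"
    lab1 <- makeLabels(matrix(up, nrow = 1,
                              dimnames = list("s", NULL)),
                       concentrations = c(256, 64, 16))
    l0 <- superBin(lab0)[1]
    l1 <- superBin(lab1)[1]
    if (!is.na(l0) && !is.na(l1)) expect_gte(l1, l0)
  }
})

test_that("concordance is the nested-positive fraction per level", {
  lab <- makeLabels(cbind(
    rep("positive", 10),
    c(rep("positive", 9), "negative"),
    c(rep("positive", 9), "ambiguous")),
    concentrations = c(256, 64, 16))
  rownames(lab@labels) <- paste0("s", 1:10)
  # plant one violator: positive at the strictest but negative below
  lab@labels[10, 3] <- "positive"
  co <- concordance(lab)
  expect_equal(unname(co), c(1, 1, 0.9))
  single <- makeLabels(matrix("positive", 3, 1,
                              dimnames = list(paste0("s", 1:3), NULL)),
                       concentrations = 64)
  expect_equal(unname(concordance(single)), 1)
})

test_that("noiseless screens nest perfectly across the ladder", {
  ex <- simulateExperiment(nSequences = 250, noiseCv = 0, seed = 77)
  lab <- suppressWarnings(labelPools(pools(ex)))
  expect_true(all(concordance(lab) == 1))
})

test_that("folds deal whole clusters round-robin", {
  set.seed(14)
  seqs <- unique(randomSequences(10))
  cl <- clusterSequences(seqs)
  sp <- splitFolds(cl, nFolds = 5, seed = 3)
  expect_equal(as.integer(table(sp$clusterFold)), rep(2L, 5))
  expect_equal(sort(unique(sp$fold)), 0:4)
  # cluster ids never span folds
  ids <- clusterIds(cl)
  expect_true(all(tapply(sp$fold[names(ids)], ids, function(x) {
    length(unique(x))
  }) == 1))
})

test_that("a giant cluster degenerates the split with a warning", {
  chain <- c(A40, vapply(1:9, function(i) {
    paste0(strrep("C", i), strrep("A", 40 - i))
  }, character(1)))
  lone <- paste0(strrep("G", 20), strrep("T", 20))
  cl <- clusterSequences(c(chain, lone))
  expect_length(representatives(cl), 2L)
  expect_warning(splitFolds(cl, nFolds = 2, seed = 1), "giant cluster")
})

test_that("no near-duplicate pair is split across train and test", {
  seqs <- plantedFamilies(nBase = 15, size = 3, maxD = 5, nNoise = 50,
                          seed = 9)
  cl <- clusterSequences(seqs)
  sp <- splitFolds(cl, seed = 9)
  D <- utils::adist(seqs)
  pairs <- which(D <= 5 & upper.tri(D), arr.ind = TRUE)
  for (r in seq_len(nrow(pairs))) {
    a <- seqs[pairs[r, 1]]
    b <- seqs[pairs[r, 2]]
    expect_equal(a %in% sp$test, b %in% sp$test)
  }
})
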