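test_that("binding fraction follows the single-site hyperbola", {
  # incubating at half the K_D puts occupancy exactly at the 1/3 gate
  for (kd in c(0.5, 8, 100, 1e4)) {
    expect_equal(bindingFraction(kd / 2, kd), 1 / 3)
  }
  expect_equal(bindingFraction(128, 128), 0.5)
  expect_equal(bindingFraction(0, 77), 0)
  expect_error(bindingFraction(10, 0), "positive")
})

test_that("binding fraction is strictly monotone in both arguments", {
  set.seed(5)
  conc <- sort(10^runif(25, -2, 4))
  kds <- sort(10^runif(25, -2, 4))
  for (kd in kds) {
    expect_true(all(diff(bindingFraction(conc, kd)) > 0))
  }
  for (tc in conc) {
    expect_true(all(diff(bindingFraction(tc, kds)) < 0))
  }
})

test_that("sort concentration maps to twice-the-concentration threshold", {
  expect_equal(kdThresholdForConcentration(256), 512)
  expect_equal(kdThresholdForConcentration(4), 8)
  expect_equal(kdThresholdForConcentration(0.5), 1)
  expect_error(kdThresholdForConcentration(0), "positive")
})

test_that("ladder arithmetic: fourfold concentrations, doubled thresholds", {
  lad <- stringencyLadder()
  expect_equal(concentrations(lad), c(256, 64, 16, 4))
  expect_equal(kdThresholds(lad), c(512, 128, 32, 8))
  ratios <- kdThresholds(lad)[-4] / kdThresholds(lad)[-1]
  expect_equal(ratios, rep(4, 3))
  expect_error(stringencyLadder(c(256, 100, 16)), "foldFactor")
})

test_that("noiseless sort partitions exactly at K_D = 2T, boundary inclusive", {
  # oracle with K_D exactly at the threshold: baseline 128, T = 64
  atBoundary <- affinityOracle(baselineKd = 128, motifs = character(0),
                               noiseSdLog = 0)
  sorted <- simulateSort(c(A40, strrep("C", 40)), atBoundary, conc = 64,
                         noiseCv = 0, beads = 5L)
  expect_equal(sum(sorted$positive), 10L) # all beads collected
  expect_length(sorted$negative, 0L)
  # just above the threshold: all negative
  above <- affinityOracle(baselineKd = 128.01, motifs = character(0),
                          noiseSdLog = 0)
  sorted2 <- simulateSort(A40, above, conc = 64, noiseCv = 0, beads = 5L)
  expect_length(sorted2$positive, 0L)
  expect_equal(sum(sorted2$negative), 5L)
  # T = 0: occupancy zero, everything negative
  sorted3 <- simulateSort(A40, atBoundary, conc = 0, noiseCv = 0)
  expect_length(sorted3$positive, 0L)
  # empty input: empty pools, no error
  empty <- simulateSort(character(0), atBoundary, conc = 64)
  expect_length(empty$positive, 0L)
  expect_length(empty$negative, 0L)
})

test_that("noiseless sort equals the K_D <= 2T rule on random oracles", {
  set.seed(11)
  for (rep in 1:25) {
    orc <- affinityOracle(baselineKd = 10^runif(1, 1, 4),
                          noiseSdLog = runif(1, 0, 1),
                          seed = sample.int(1e6, 1))
    seqs <- randomSequences(40)
    tc <- 10^runif(1, 0, 3)
    sorted <- simulateSort(seqs, orc, tc, noiseCv = 0, beads = 1L,
                           seed = rep)
    expected <- seqs[kdOf(orc, seqs) <= 2 * tc]
    expect_setequal(names(sorted$positive), expected)
  }
})

test_that("sequencing sampling is multinomial over beads", {
  expect_equal(simulateSequencing(c(s1 = 1L), 100), c(s1 = 100L))
  expect_length(simulateSequencing(c(s1 = 1L), 0), 0L)
  expect_error(simulateSequencing(integer(0), 10), "empty pool")
  cnt <- simulateSequencing(c(a = 1L, b = 1L), 1e5, seed = 4)
  expect_equal(sum(cnt), 1e5)
  # each count within 5 binomial s.d. of its expectation
  expect_lt(abs(cnt["a"] - 5e4), 5 * sqrt(1e5 * 0.25))
})

test_that("single-round noiseless screen recovers the oracle threshold set", {
  lad <- stringencyLadder(concentrations = 64, foldFactor = 4)
  ex <- simulateExperiment(nSequences = 300, ladder = lad, rounds = 1,
                           noiseCv = 0, seed = 21)
  lib <- trueLibrary(ex)
  pos <- rownames(poolCounts(pools(ex)))[
    poolCounts(pools(ex))[, "R1_64nM_pos"] > 0]
  expect_setequal(pos, lib$sequence[lib$kd <= 128])
})

test_that("simulation is reproducible and enrichment never adds sequences", {
  ex1 <- simulateExperiment(nSequences = 150, rounds = 2, noiseCv = 0,
                            seed = 31)
  ex2 <- simulateExperiment(nSequences = 150, rounds = 2, noiseCv = 0,
                            seed = 31)
  expect_identical(poolCounts(pools(ex1)), poolCounts(pools(ex2)))
  info <- poolInfo(pools(ex1))
  cnt <- poolCounts(pools(ex1))
  # round-2 positives at a level sorted in both rounds are a subset of
  # round-1 positives at that level
  shared <- intersect(info$concentration[info$round == 1],
                      info$concentration[info$round == 2])
  for (conc in shared) {
    p1 <- rownames(cnt)[cnt[, sprintf("R1_%snM_pos", format(conc))] > 0]
    p2 <- rownames(cnt)[cnt[, sprintf("R2_%snM_pos", format(conc))] > 0]
    expect_true(all(p2 %in% p1))
  }
})

test_that("every pooled sequence belongs to the library", {
  ex <- smallSim()
  expect_true(all(rownames(poolCounts(pools(ex))) %in%
                    trueLibrary(ex)$sequence))
  expect_true(validObject(ex))
})
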