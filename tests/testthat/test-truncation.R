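test_that("core embedding fills homopolymer flanks to the frame length", {
  expect_equal(embedCore("TGG", 0, "A"), paste0("TGG", strrep("A", 37)))
  expect_equal(embedCore("TGG", 37, "C"), paste0(strrep("C", 37), "TGG"))
  full <- strrep("G", 40)
  expect_equal(embedCore(full, 0, "A"), full) # length-40 core is itself
  expect_error(embedCore("TGG", 38, "A"), "start")
  expect_error(embedCore("TGG", -1, "A"), "start")
})

test_that("scans produce 4 * (L - l + 1) variants per core", {
  constScorer <- function(s) rep(1, length(s))
  scans <- scanCores(strrep("ACGT", 10), constScorer, lengths = c(39, 40),
                     minLength = 15)
  by_l <- split(scans, vapply(scans, function(s) nchar(s@core),
                              integer(1)))
  expect_length(by_l[["39"]], 2L) # 40 - 39 + 1 cores
  for (s in by_l[["39"]]) expect_length(s@scores, 8L) # 4 * 2
  expect_length(by_l[["40"]], 1L)
  expect_length(by_l[["40"]][[1]]@scores, 4L) # degenerate all-position
  # scanned default lengths obey the formula
  set.seed(3)
  scans2 <- scanCores(randomSequences(1), constScorer)
  for (s in scans2) {
    expect_length(s@scores, 4 * (40 - nchar(s@core) + 1))
  }
})

test_that("a motif-presence scorer marks every motif-containing core", {
  ind <- function(s) as.numeric(grepl("TGGATAG", s, fixed = TRUE))
  full <- paste0(strrep("C", 10), "TGGATAG", strrep("C", 23))
  scans <- scanCores(full, ind, lengths = c(15, 23))
  for (s in scans) {
    if (grepl("TGGATAG", s@core, fixed = TRUE)) {
      expect_true(all(s@scores == 1))
    } else {
      # flank-bridge artifacts aside, the median stays at 0
      expect_equal(s@median, 0)
    }
  }
})

test_that("core ranking orders by the chosen statistic with stable ties", {
  mk <- function(core, med, v) {
    new("CoreScan", core = core, frameLength = 40L,
        scores = matrix(med, 4, 40 - nchar(core) + 1), median = med,
        variance = v)
  }
  scans <- list(mk(strrep("A", 20), 0.5, 0.1), mk(strrep("C", 20), 0.9, 0.3),
                mk(strrep("G", 15), 0.9, 0.0))
  r <- rankCores(scans, "max_median")
  # equal medians: shorter length first
  expect_equal(r$core[1:2], c(strrep("G", 15), strrep("C", 20)))
  expect_equal(rankCores(scans, "min_variance")$core[1],
               strrep("G", 15))
  expect_equal(rankCores(scans, "min_median")$core[1], strrep("A", 20))
  # constant scorer: all variances zero, order falls to the tie-break
  constScorer <- function(s) rep(2, length(s))
  rc <- rankCores(scanCores(strrep("ACGT", 10), constScorer,
                            lengths = c(15)), "min_variance")
  expect_equal(rc$core, sort(rc$core))
})

test_that("oracle-guided scan recovers the planted motif at every length", {
  orc <- affinityOracle(seed = 12)
  scorer <- function(s) -log10(kdOf(orc, s))
  set.seed(12)
  full <- randomSequences(1)
  substr(full, 15, 21) <- "TGGATAG"
  ranked <- rankCores(scanCores(full, scorer))
  for (l in unique(ranked$length)) {
    top <- ranked[ranked$length == l, ][1, ]
    expect_true(grepl("TGGATAG", top$core, fixed = TRUE))
  }
})

test_that("containment: top cores persist inside larger truncations", {
  orc <- affinityOracle(seed = 21)
  scorer <- function(s) -log10(kdOf(orc, s))
  set.seed(21)
  full <- randomSequences(1)
  substr(full, 18, 24) <- "TGGATAG"
  ranked <- rankCores(scanCores(full, scorer, lengths = c(15, 23, 31)))
  top15 <- ranked[ranked$length == 15, ][1, "core"]
  for (l in c(23, 31)) {
    atL <- ranked[ranked$length == l, ]
    containing <- grepl(top15, atL$core, fixed = TRUE)
    noMotif <- !grepl("TGGATAG", atL$core, fixed = TRUE)
    if (any(containing) && any(noMotif)) {
      # super-cores carrying the top 15-mer stay clearly above the
      # motif-free cores of their length
      expect_gte(min(atL$median[containing]),
                 median(atL$median[noMotif]))
    }
  }
})

test_that("k-mer enrichment finds a planted 7-mer verbatim", {
  set.seed(31)
  pos <- randomSequences(60)
  st <- sample.int(34, 60, replace = TRUE)
  substr(pos, st, st + 6) <- "TGGATAG"
  bg <- randomSequences(400)
  tab <- differentialKmerEnrichment(pos, bg, kRange = 5:8)
  expect_equal(attr(tab, "consensus"), "TGGATAG")
  expect_equal(attr(tab, "consensusK"), 7L)
  expect_lt(tab$pBonferroni[tab$kmer == "TGGATAG"], 1e-20)
})

test_that("matched positive and background pools yield no survivors", {
  set.seed(32)
  pos <- randomSequences(40)
  bg <- randomSequences(400)
  tab <- differentialKmerEnrichment(pos, bg, kRange = 4:6)
  expect_true(is.na(attr(tab, "consensus")))
  expect_true(all(tab$pBonferroni > 0.05))
  # identical sets: every log-odds is exactly zero
  same <- differentialKmerEnrichment(pos, pos, kRange = 4:5)
  expect_true(all(abs(same$logOdds) < 1e-12))
})

test_that("the hypergeometric tail equals Fisher's one-sided exact test", {
  cells <- list(c(20, 2, 30, 48), c(5, 5, 20, 20), c(10, 0, 15, 40))
  for (cc in cells) {
    a <- cc[1]; b <- cc[2]; nPos <- cc[1] + cc[3]; nBg <- cc[2] + cc[4]
    p1 <- phyper(a - 1, nPos, nBg, a + b, lower.tail = FALSE)
    p2 <- stats::fisher.test(matrix(c(a, b, nPos - a, nBg - b), 2),
                             alternative = "greater")$p.value
    expect_equal(p1, p2, tolerance = 1e-12)
  }
})
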