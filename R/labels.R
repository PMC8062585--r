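#' Normalize sequencing counts to pool fractions
#'
#' Sequencing counts are normalized to the total reads of the experiment.
#' The default (`per = "pool"`) divides each pool's counts by that pool's
#' total so fractions are comparable across pools of different depth and
#' sum to one per pool; `per = "experiment"` divides by the grand total
#' instead.
#'
#' @param counts a [PoolSet] or a numeric count matrix (sequences x
#'   pools).
#' @param per `"pool"` (default) or `"experiment"`.
#' @return numeric matrix of fractions, same shape as the counts.
#' @export
normalizeCounts <- function(counts, per = c("pool", "experiment")) {
  per <- match.arg(per)
  mat <- if (is(counts, "PoolSet")) poolCounts(counts) else counts
  if (per == "pool") {
    tot <- colSums(mat)
    if (any(tot == 0)) {
      warning("pool(s) with zero total reads: ",
              paste(colnames(mat)[tot == 0], collapse = ", "),
              "; their fractions are set to 0")
      tot[tot == 0] <- 1
    }
    sweep(mat, 2L, tot, "/")
  } else {
    g <- sum(mat)
    if (g == 0) {
      warning("experiment has zero total reads; fractions set to 0")
      g <- 1
    }
    mat / g
  }
}

#' Ternary stringency labels from paired positive/negative pools
#'
#' For each stringency level (one positive and one negative pool at the
#' same concentration and round), a sequence is labeled `positive` when it
#' is reliably detected in the positive pool — sequencing count of at
#' least `coverageFraction` (default 20%) of the pool's expected bead
#' coverage — and is more prevalent there than in the negative pool by
#' normalized sequencing fraction. The symmetric rule (reliable detection
#' in the negative pool and a reversed prevalence inequality) labels it
#' `negative`; everything else is `ambiguous`.
#'
#' @param poolSet a [PoolSet].
#' @param round which screening round's pools to label (default: the
#'   highest round present).
#' @param coverageFraction detection threshold as a fraction of expected
#'   bead coverage (default 0.2).
#' @return a [StringencyLabels] over the sequences of `poolSet`, columns
#'   ordered weakest to strongest stringency.
#' @export
labelPools <- function(poolSet, round = NULL, coverageFraction = 0.2) {
  info <- poolInfo(poolSet)
  if (is.null(round)) round <- max(info$round)
  info <- info[info$round == round, , drop = FALSE]
  conc <- sort(unique(info$concentration), decreasing = TRUE)
  mat <- poolCounts(poolSet)
  frac <- normalizeCounts(poolSet)
  lab <- matrix("ambiguous", nrow = nrow(mat), ncol = length(conc),
                dimnames = list(rownames(mat),
                                paste0(format(conc, trim = TRUE), "nM")))
  for (li in seq_along(conc)) {
    posPool <- rownames(info)[info$concentration == conc[li] &
                                info$polarity == "positive"]
    negPool <- rownames(info)[info$concentration == conc[li] &
                                info$polarity == "negative"]
    if (length(posPool) != 1L || length(negPool) != 1L) {
      stop("round ", round, " at ", conc[li],
           " nM lacks a paired positive/negative pool")
    }
    minPos <- coverageFraction * info[posPool, "expectedCoverage"]
    minNeg <- coverageFraction * info[negPool, "expectedCoverage"]
    isPos <- mat[, posPool] >= minPos & frac[, posPool] > frac[, negPool]
    isNeg <- mat[, negPool] >= minNeg & frac[, negPool] > frac[, posPool]
    lab[isPos, li] <- "positive"
    lab[isNeg & !isPos, li] <- "negative"
  }
  new("StringencyLabels", labels = lab, concentrations = conc)
}

#' @rdname labelMatrix
#' @export
setMethod("labelMatrix", "StringencyLabels", function(object) object@labels)

#' @rdname sequences
#' @export
setMethod("sequences", "StringencyLabels", function(object) {
  rownames(object@labels)
})

#' @rdname concentrations
#' @export
setMethod("concentrations", "StringencyLabels", function(object) {
  object@concentrations
})

setMethod("show", "StringencyLabels", function(object) {
  cat("StringencyLabels:", nrow(object@labels), "sequences x",
      ncol(object@labels), "stringency levels\n")
  print(apply(object@labels, 2L, function(x) table(factor(
    x, levels = c("positive", "negative", "ambiguous")))))
})

#' Collapse stringency labels into a single SuperBin affinity level
#'
#' Summarizes all stringency experiments with one number. With `s`
#' stringency levels (ordered weakest to strongest) a sequence that
#' passes the first `p` consecutive levels gets level `2 * p`, plus 1
#' when it is additionally ambiguous (borderline) at the next stricter
#' level — yielding the 7 levels 0..6 for the canonical three-stringency
#' screen. Sequences with conflicting labels (positive at some level but
#' negative at a weaker one) and fully ambiguous sequences are excluded.
#'
#' @param labels a [StringencyLabels].
#' @return named integer vector of levels (names = sequences); excluded
#'   sequences are `NA`.
#' @export
superBin <- function(labels) {
  lab <- labelMatrix(labels)
  s <- ncol(lab)
  out <- rep(NA_integer_, nrow(lab))
  names(out) <- rownames(lab)
  isPos <- lab == "positive"
  isNeg <- lab == "negative"
  isAmb <- lab == "ambiguous"
  # conflict: positive at level j, negative at some weaker i < j
  conflict <- rep(FALSE, nrow(lab))
  if (s > 1L) {
    negBefore <- t(apply(isNeg, 1L, cumsum)) > 0
    conflict <- rowSums(isPos[, -1L, drop = FALSE] &
                          negBefore[, -s, drop = FALSE]) > 0
  }
  allAmb <- rowSums(isAmb) == s
  # consecutive passes from the weakest level
  passRun <- apply(isPos, 1L, function(x) {
    r <- 0L
    for (v in x) { if (!v) break; r <- r + 1L }
    r
  })
  lvl <- 2L * passRun
  nextAmb <- passRun < s &
    isAmb[cbind(seq_len(nrow(lab)), pmin(passRun + 1L, s))]
  lvl <- lvl + as.integer(nextAmb)
  keep <- !conflict & !allAmb
  out[keep] <- lvl[keep]
  out
}

#' Per-stringency nesting concordance
#'
#' For each stringency level, the fraction of its positive sequences that
#' are also positive at every weaker level. In a noise-free screen the
#' positive sets nest perfectly and every fraction is 1. Levels with no
#' positives (including the weakest level) are vacuously concordant.
#'
#' @param labels a [StringencyLabels].
#' @return named numeric vector of fractions, one per level.
#' @export
concordance <- function(labels) {
  lab <- labelMatrix(labels)
  isPos <- lab == "positive"
  out <- numeric(ncol(lab))
  names(out) <- colnames(lab)
  for (j in seq_len(ncol(lab))) {
    pos <- which(isPos[, j])
    if (j == 1L || length(pos) == 0L) {
      out[j] <- 1
    } else {
      nested <- rowSums(isPos[pos, seq_len(j - 1L), drop = FALSE]) == j - 1L
      out[j] <- mean(nested)
    }
  }
  out
}

#' Deal clusters into cross-validation folds
#'
#' Clusters are shuffled with the seed and dealt round-robin into
#' `nFolds` folds, so fold sizes differ by at most one cluster and no
#' cluster ever spans folds; the designated test fold holds out ~1/nFolds
#' of the clusters (20% by default).
#'
#' @param clusters a [ClusterAssignment].
#' @param nFolds number of folds (default 5).
#' @param testFold fold index in `0:(nFolds-1)` designated as the test
#'   set (default 0).
#' @param seed shuffle seed.
#' @return list with `clusterFold` (integer fold per cluster id),
#'   `fold` (named integer fold per sequence), `testFold`, and character
#'   vectors `train` / `test` of sequences.
#' @export
splitFolds <- function(clusters, nFolds = 5L, testFold = 0L, seed = 1L) {
  stopifnot(testFold >= 0L, testFold < nFolds)
  k <- length(representatives(clusters))
  set.seed(deriveSeed(seed, "folds"))
  shuffled <- sample.int(k)
  clusterFold <- integer(k)
  clusterFold[shuffled] <- (seq_len(k) - 1L) %% nFolds
  if (k < nFolds) {
    warning("fewer clusters (", k, ") than folds (", nFolds,
            "); some folds are empty")
  }
  ids <- clusterIds(clusters)
  fold <- clusterFold[ids]
  names(fold) <- names(ids)
  maxShare <- max(table(factor(fold, levels = 0:(nFolds - 1L)))) /
    max(1L, length(fold))
  if (maxShare > 0.9) {
    warning("a single fold holds ", round(100 * maxShare),
            "% of sequences (giant cluster); split is degenerate")
  }
  list(clusterFold = clusterFold, fold = fold, testFold = as.integer(testFold),
       train = names(fold)[fold != testFold],
       test = names(fold)[fold == testFold])
}
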