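#' Equilibrium binding fraction of an aptamer
#'
#' Single-site occupancy Fr = \[T\] / (\[T\] + K_D): the fraction of
#' displayed aptamer molecules bound at target concentration \[T\]. Bead
#' fluorescence in a particle-display sort reports this fraction,
#' F = F_max * Fr.
#'
#' @param conc target concentration \[T\] in nM (>= 0); vectorized.
#' @param kd dissociation constant in nM (> 0); vectorized.
#' @return occupancy fraction in \[0, 1).
#' @examples
#' bindingFraction(64, 128) # K_D = 2[T] -> exactly 1/3
#' @export
bindingFraction <- function(conc, kd) {
  if (any(kd <= 0)) stop("kd must be positive")
  if (any(conc < 0)) stop("conc must be non-negative")
  conc / (conc + kd)
}

#' K_D threshold isolated by a sort concentration
#'
#' Incubating at \[T\] with the FACS gate at F_max/3 collects exactly the
#' aptamers with K_D <= 2\[T\] (since Fr >= 1/3 iff K_D <= 2\[T\]).
#'
#' @param conc target concentration in nM (> 0); vectorized.
#' @return the isolated K_D threshold, 2 * \[T\] (nM).
#' @examples
#' kdThresholdForConcentration(c(256, 64, 16, 4)) # 512 128 32 8
#' @export
kdThresholdForConcentration <- function(conc) {
  if (any(conc <= 0)) stop("conc must be positive")
  2 * conc
}

#' Simulate one FACS sort of an aptamer bead pool
#'
#' Each bead displays one sequence and fluoresces at
#' F = F_max * Fr * (1 + eps), eps ~ Normal(0, noiseCv). Beads with
#' F >= gateFraction * F_max are collected as the positive population,
#' the rest as the negative population (gate boundary inclusive). With
#' `noiseCv = 0` a sequence is positive iff its K_D <= 2 * `conc` (for the
#' default 1/3 gate). Per-sequence positive bead numbers are drawn
#' binomially with the exact per-bead gate-crossing probability.
#'
#' @param sequences character vector of displayed sequences.
#' @param oracle an [AffinityOracle] supplying true K_D values.
#' @param conc target concentration in nM.
#' @param gateFraction collection gate as a fraction of F_max (default 1/3).
#' @param noiseCv coefficient of variation of multiplicative fluorescence
#'   noise (default 0.1; 0 = deterministic gating).
#' @param beads bead count per sequence: scalar or vector parallel to
#'   `sequences` (default 10).
#' @param seed integer RNG seed for the noise draws.
#' @return list with named integer vectors `positive` and `negative`
#'   (bead counts per sequence; zero-count entries dropped).
#' @export
simulateSort <- function(sequences, oracle, conc, gateFraction = 1 / 3,
                         noiseCv = 0.1, beads = 10L, seed = 1L) {
  stopifnot(gateFraction > 0, gateFraction < 1, noiseCv >= 0)
  if (length(sequences) == 0L) {
    return(list(positive = integer(0), negative = integer(0)))
  }
  beads <- rep_len(as.integer(beads), length(sequences))
  kd <- kdOf(oracle, sequences)
  fr <- bindingFraction(conc, kd)
  # P(F >= gate * Fmax) per bead; inclusive boundary
  if (noiseCv == 0) {
    p <- as.numeric(fr >= gateFraction)
  } else {
    p <- ifelse(fr == 0, 0, 1 - pnorm((gateFraction / fr - 1) / noiseCv))
  }
  set.seed(deriveSeed(seed, "sort"))
  pos <- rbinom(length(sequences), beads, p)
  neg <- beads - pos
  list(positive = setNames(pos, sequences)[pos > 0L],
       negative = setNames(neg, sequences)[neg > 0L])
}

#' Simulate NGS read sampling of a sorted bead pool
#'
#' Draws `totalReads` sequencing reads multinomially over the beads of a
#' pool, proportional to bead abundance.
#'
#' @param pool named integer vector: bead count per sequence.
#' @param totalReads number of reads to draw (>= 0).
#' @param seed integer RNG seed.
#' @return named integer vector of read counts (sums to `totalReads`;
#'   zero-count sequences dropped).
#' @export
simulateSequencing <- function(pool, totalReads, seed = 1L) {
  stopifnot(totalReads >= 0)
  if (totalReads == 0) return(integer(0))
  if (length(pool) == 0L) {
    stop("cannot sequence an empty pool with totalReads > 0")
  }
  set.seed(deriveSeed(seed, "sequencing"))
  counts <- as.integer(rmultinom(1L, as.integer(totalReads),
                                 prob = pool / sum(pool)))
  setNames(counts, names(pool))[counts > 0L]
}

#' Simulate a multi-round particle-display screen
#'
#' Generates a complete synthetic screen: a random fixed-length library
#' with ground-truth affinities from `oracle`, fluorescence-gated sorts
#' across the stringency ladder, and multinomial sequencing of every
#' positive and negative pool. With two or more rounds, round 1 sorts the
#' full library at the weaker stringencies (by default all but the
#' strictest level), the round-1 positive pools are mixed at equal total
#' bead mass (1:1) and resampled abundance-proportionally to form the
#' round-2 input, and later rounds sort at every level.
#'
#' A configurable fraction of the library carries a planted oracle motif
#' (inserted at a random position), emulating the small high-affinity
#' component of a real screening library.
#'
#' @param nSequences library size (default 2500).
#' @param seqLength variable-region length (default 40).
#' @param ladder a [StringencyLadder].
#' @param rounds number of sort-amplify rounds (default 1).
#' @param oracle an [AffinityOracle] (default [affinityOracle()] seeded
#'   from `seed`).
#' @param motifFraction fraction of library sequences seeded with the
#'   oracle's first planted motif (default 0.1).
#' @param noiseCv fluorescence noise CV passed to [simulateSort()]
#'   (default 0.1).
#' @param beadsPerSequence beads displayed per library sequence
#'   (default 10).
#' @param roundLevels optional list: for each round, integer indices into
#'   `concentrations(ladder)` to sort at. Default: round 1 uses all but
#'   the strictest level when `rounds >= 2` (all levels otherwise);
#'   later rounds use all levels.
#' @param seed experiment seed; all stage RNG streams derive from it.
#' @return a [SimulatedExperiment].
#' @examples
#' ex <- simulateExperiment(nSequences = 200, ladder = stringencyLadder(),
#'                          seed = 7)
#' poolInfo(pools(ex))
#' @export
simulateExperiment <- function(nSequences = 2500, seqLength = 40L,
                               ladder = stringencyLadder(), rounds = 1L,
                               oracle = NULL, motifFraction = 0.1,
                               noiseCv = 0.1, beadsPerSequence = 10L,
                               roundLevels = NULL, seed = 1L) {
  stopifnot(rounds >= 1L)
  if (is.null(oracle)) oracle <- affinityOracle(seed = deriveSeed(seed, "oracle"))
  conc <- concentrations(ladder)
  nLev <- length(conc)
  if (is.null(roundLevels)) {
    r1 <- if (rounds >= 2L && nLev >= 2L) seq_len(nLev - 1L) else seq_len(nLev)
    roundLevels <- c(list(r1), rep(list(seq_len(nLev)), rounds - 1L))
  }
  stopifnot(length(roundLevels) == rounds)

  set.seed(deriveSeed(seed, "library"))
  lib <- randomSequences(nSequences, seqLength)
  if (motifFraction > 0 && length(oracle@motifs)) {
    motif <- oracle@motifs[1L]
    nPlant <- round(motifFraction * nSequences)
    idx <- sample.int(nSequences, nPlant)
    starts <- sample.int(seqLength - nchar(motif) + 1L, nPlant,
                         replace = TRUE)
    substr(lib[idx], starts, starts + nchar(motif) - 1L) <- motif
  }
  lib <- unique(lib)
  kd <- kdOf(oracle, lib)

  input <- setNames(rep(as.integer(beadsPerSequence), length(lib)), lib)
  totalBeads <- sum(input)
  counts <- list()
  info <- list()
  for (r in seq_len(rounds)) {
    levels <- roundLevels[[r]]
    posPools <- list()
    for (li in levels) {
      sorted <- simulateSort(names(input), oracle, conc[li],
                             gateFraction = gateFraction(ladder),
                             noiseCv = noiseCv, beads = unname(input),
                             seed = deriveSeed(seed, paste0("sort_r", r,
                                                            "_l", li)))
      posPools[[as.character(li)]] <- sorted$positive
      for (pol in c("positive", "negative")) {
        beadPool <- sorted[[pol]]
        nm <- sprintf("R%d_%snM_%s", r, format(conc[li]),
                      if (pol == "positive") "pos" else "neg")
        reads <- round(expectedCoverage(ladder) * length(beadPool))
        cnt <- if (reads > 0 && length(beadPool)) {
          simulateSequencing(beadPool, reads,
                             seed = deriveSeed(seed, paste0("seq_", nm)))
        } else integer(0)
        counts[[nm]] <- cnt
        info[[nm]] <- data.frame(pool = nm, round = r,
                                 concentration = conc[li], polarity = pol,
                                 totalReads = sum(cnt),
                                 expectedCoverage = expectedCoverage(ladder))
      }
    }
    if (r < rounds) {
      # 1:1 mix of this round's positive pools, then proportional resampling
      nonEmpty <- posPools[vapply(posPools, length, integer(1)) > 0L]
      if (length(nonEmpty) == 0L) {
        warning("no positive beads in round ", r,
                "; subsequent rounds run on empty input")
        input <- integer(0)
        next
      }
      mix <- numeric(0)
      for (p in nonEmpty) {
        w <- p / sum(p)
        mix[names(w)] <- ifelse(is.na(mix[names(w)]), 0, mix[names(w)]) + w
      }
      set.seed(deriveSeed(seed, paste0("amplify_r", r)))
      resampled <- as.integer(rmultinom(1L, totalBeads, prob = mix / sum(mix)))
      input <- setNames(resampled, names(mix))[resampled > 0L]
    }
  }

  pools <- .buildPoolSet(counts, do.call(rbind, info))
  new("SimulatedExperiment",
      library = data.frame(sequence = lib, kd = kd),
      pools = pools, ladder = ladder, seed = as.integer(seed),
      params = list(nSequences = nSequences, seqLength = seqLength,
                    rounds = rounds, motifFraction = motifFraction,
                    noiseCv = noiseCv, beadsPerSequence = beadsPerSequence,
                    roundLevels = roundLevels, oracle = oracle))
}

# assemble a PoolSet from a list of named count vectors + pool metadata
.buildPoolSet <- function(counts, info) {
  seqs <- sort(unique(unlist(lapply(counts, names), use.names = FALSE)))
  mat <- matrix(0L, nrow = length(seqs), ncol = length(counts),
                dimnames = list(seqs, names(counts)))
  for (nm in names(counts)) {
    cnt <- counts[[nm]]
    if (length(cnt)) mat[names(cnt), nm] <- as.integer(cnt)
  }
  rownames(info) <- info$pool
  new("PoolSet", SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = mat),
    colData = S4Vectors::DataFrame(info[colnames(mat), , drop = FALSE])))
}

#' Pool count matrix of a PoolSet
#' @param object a [PoolSet].
#' @return integer matrix, sequences x pools.
#' @export
poolCounts <- function(object) {
  SummarizedExperiment::assay(object, "counts")
}

#' Pool metadata of a PoolSet
#' @param object a [PoolSet].
#' @return data.frame with round, concentration, polarity, totalReads,
#'   expectedCoverage per pool.
#' @export
poolInfo <- function(object) {
  as.data.frame(SummarizedExperiment::colData(object))
}

#' @rdname sequences
#' @export
setMethod("sequences", "SimulatedExperiment", function(object) {
  object@library$sequence
})

#' Pools of a simulated experiment
#' @param object a [SimulatedExperiment].
#' @return the [PoolSet] of sequencing counts.
#' @export
pools <- function(object) object@pools

#' Ground-truth library of a simulated experiment
#' @param object a [SimulatedExperiment].
#' @return data.frame with `sequence` and true `kd` (nM).
#' @export
trueLibrary <- function(object) object@library

setMethod("show", "SimulatedExperiment", function(object) {
  cat("SimulatedExperiment:", nrow(object@library), "library sequences,",
      ncol(object@pools), "pools, seed", object@seed, "\n")
  print(object@ladder)
})

#' Ground-truth oracle of a simulated experiment
#' @param object a [SimulatedExperiment].
#' @return the [AffinityOracle] that generated the library affinities.
#' @export
simOracle <- function(object) object@params$oracle
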