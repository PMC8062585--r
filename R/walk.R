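#' Walk configuration
#'
#' Defaults follow the selection protocol: five rounds, 10,000 sampled
#' mutants per round each up to 4 substitutions from a parent, the top
#' five mutants per round emitted as candidates, and the top 200 mutants
#' carried forward as the next parent set.
#'
#' @param rounds walk rounds (default 5).
#' @param mutantsPerRound mutants sampled per round (default 10000).
#' @param maxSubstitutions maximum substitutions per mutant from its
#'   parent (default 4).
#' @param parentCap parent-set size carried to the next round
#'   (default 200).
#' @param selectedPerRound candidates emitted per round (default 5).
#' @return a validated list of walk parameters.
#' @export
walkConfig <- function(rounds = 5L, mutantsPerRound = 10000L,
                       maxSubstitutions = 4L, parentCap = 200L,
                       selectedPerRound = 5L) {
  cfg <- list(rounds = as.integer(rounds),
              mutantsPerRound = as.integer(mutantsPerRound),
              maxSubstitutions = as.integer(maxSubstitutions),
              parentCap = as.integer(parentCap),
              selectedPerRound = as.integer(selectedPerRound))
  stopifnot(cfg$rounds >= 0L, cfg$mutantsPerRound >= 1L,
            cfg$maxSubstitutions >= 0L,
            cfg$selectedPerRound <= cfg$parentCap,
            cfg$parentCap <= cfg$mutantsPerRound)
  cfg
}

#' Screen random sequences in silico for walk seeds
#'
#' Generates `nCandidates` uniform random 40-mers in constant-memory
#' chunks, scores each with `scorer`, and returns the top
#' `ceiling(nCandidates * topFraction)` scorers (ties broken
#' lexicographically), emulating model pre-screening of up to 1e9 random
#' aptamers at a 0.0005% keep rate.
#'
#' @param scorer function(character) -> numeric scores.
#' @param nCandidates total random candidates to screen.
#' @param topFraction fraction kept, in (0, 1).
#' @param seqLength candidate length (default 40).
#' @param chunkSize candidates per streamed chunk (default 1e5).
#' @param seed RNG seed.
#' @return character vector of seed sequences, best score first; scores
#'   attached as names.
#' @export
screenRandomSeeds <- function(scorer, nCandidates, topFraction,
                              seqLength = 40L, chunkSize = 1e5L,
                              seed = 1L) {
  stopifnot(topFraction > 0, topFraction < 1, nCandidates >= 1)
  keep <- as.integer(ceiling(nCandidates * topFraction))
  set.seed(deriveSeed(seed, "screen"))
  bestSeq <- character(0)
  bestScore <- numeric(0)
  remaining <- nCandidates
  while (remaining > 0) {
    m <- as.integer(min(chunkSize, remaining))
    seqs <- randomSequences(m, seqLength)
    scores <- scorer(seqs)
    allSeq <- c(bestSeq, seqs)
    allScore <- c(bestScore, scores)
    ord <- order(-allScore, allSeq)[seq_len(min(keep, length(allSeq)))]
    bestSeq <- allSeq[ord]
    bestScore <- allScore[ord]
    remaining <- remaining - m
  }
  setNames(bestSeq, format(bestScore))
}

#' Randomly mutate a sequence by up to a fixed number of substitutions
#'
#' The number of substituted positions is drawn uniformly from
#' `0:maxSubstitutions`, positions are chosen without replacement, and
#' each replacement base is uniform over the three alternatives (the
#' original base is never re-inserted at a chosen position). The Hamming
#' distance to the input is therefore at most `maxSubstitutions`.
#'
#' @param sequence a single DNA sequence.
#' @param maxSubstitutions maximum substitutions (default 4).
#' @param n number of independent mutants to draw (default 1).
#' @return character vector of `n` mutants.
#' @export
mutateSequence <- function(sequence, maxSubstitutions = 4L, n = 1L) {
  L <- nchar(sequence)
  base <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  out <- character(n)
  nSub <- sample.int(maxSubstitutions + 1L, n, replace = TRUE) - 1L
  for (i in seq_len(n)) {
    if (nSub[i] == 0L) {
      out[i] <- sequence
      next
    }
    chars <- base
    pos <- sample.int(L, nSub[i])
    for (p in pos) {
      chars[p] <- sample(setdiff(DNA_BASES, chars[p]), 1L)
    }
    out[i] <- paste0(chars, collapse = "")
  }
  out
}

# shared mutate-sample-select engine for guided and random walks
.runWalk <- function(seed_sequence, scorer, config, guided, provenance,
                     seed) {
  set.seed(deriveSeed(seed, if (guided) "walk" else "randomwalk"))
  rows <- list(data.frame(round = 0L, parent = NA_character_,
                          mutant = seed_sequence,
                          score = if (guided) scorer(seed_sequence)
                                  else NA_real_,
                          selected = TRUE))
  parents <- seed_sequence
  for (r in seq_len(config$rounds)) {
    pIdx <- sample.int(length(parents), config$mutantsPerRound,
                       replace = TRUE)
    mutants <- character(config$mutantsPerRound)
    for (pi in unique(pIdx)) {
      which_i <- which(pIdx == pi)
      mutants[which_i] <- mutateSequence(parents[pi],
                                         config$maxSubstitutions,
                                         n = length(which_i))
    }
    # distance-bound invariant: substitution-only mutation from a parent
    stopifnot(all(nchar(mutants) == nchar(seed_sequence)))
    if (guided) {
      scores <- scorer(mutants)
      ord <- order(-scores, mutants)
    } else {
      scores <- rep(NA_real_, length(mutants))
      ord <- sample.int(length(mutants))
    }
    selected <- logical(length(mutants))
    selected[ord[seq_len(config$selectedPerRound)]] <- TRUE
    rows[[r + 1L]] <- data.frame(round = r, parent = parents[pIdx],
                                 mutant = mutants, score = scores,
                                 selected = selected)
    parents <- mutants[ord[seq_len(min(config$parentCap,
                                       length(mutants)))]]
  }
  new("WalkTrajectory", seedSequence = seed_sequence,
      provenance = provenance, guided = guided,
      table = do.call(rbind, rows), config = config)
}

#' Model-guided mutation walk from a seed sequence
#'
#' Iterative in-silico selection: each round samples
#' `config$mutantsPerRound` mutants (parent drawn uniformly per mutant,
#' up to `config$maxSubstitutions` substitutions), scores them with
#' `scorer`, emits the top `selectedPerRound` as candidates and carries
#' the top `parentCap` mutants forward as the next parent set. Ties are
#' broken by score descending then lexicographic sequence order.
#'
#' @param seedSequence the starting sequence.
#' @param scorer function(character) -> numeric (e.g.
#'   `function(s) affinityScore(model, s)`).
#' @param config a [walkConfig()].
#' @param provenance seed provenance tag: `"random"`, `"experimental"`
#'   or `"ml_screened"`.
#' @param seed RNG seed.
#' @return a [WalkTrajectory].
#' @export
guidedWalk <- function(seedSequence, scorer, config = walkConfig(),
                       provenance = "random", seed = 1L) {
  .runWalk(seedSequence, scorer, config, guided = TRUE,
           provenance = provenance, seed = seed)
}

#' Random-walk baseline
#'
#' Identical mutant sampling to [guidedWalk()] but with uniform-random
#' selection of emitted candidates and of the next parent set, so the
#' only difference from the guided walk is model guidance.
#'
#' @inheritParams guidedWalk
#' @return a [WalkTrajectory].
#' @export
randomWalk <- function(seedSequence, config = walkConfig(),
                       provenance = "random", seed = 1L) {
  .runWalk(seedSequence, scorer = NULL, config, guided = FALSE,
           provenance = provenance, seed = seed)
}

#' @rdname candidates
#' @param rounds restrict to these walk rounds (default: all rounds >= 1;
#'   round 0 is the seed itself).
#' @export
setMethod("candidates", "WalkTrajectory", function(object, rounds = NULL) {
  tab <- object@table
  keep <- tab$selected & tab$round > 0L
  if (!is.null(rounds)) keep <- keep & tab$round %in% rounds
  unique(tab$mutant[keep])
})

#' Walk table accessor
#' @param object a [WalkTrajectory].
#' @return the per-mutant data.frame (round, parent, mutant, score,
#'   selected).
#' @export
walkTable <- function(object) object@table

setMethod("show", "WalkTrajectory", function(object) {
  tab <- object@table
  cat(if (object@guided) "Guided" else "Random", "WalkTrajectory (",
      object@provenance, " seed), ", max(tab$round), " rounds, ",
      sum(tab$round > 0), " mutants sampled\n", sep = "")
  if (object@guided && any(tab$round > 0)) {
    best <- vapply(split(tab$score[tab$round > 0],
                         tab$round[tab$round > 0]), max, numeric(1))
    cat("  best score by round:", paste(signif(best, 4), collapse = ", "),
        "\n")
  }
})

#' Evaluate walk candidates against a ground-truth oracle
#'
#' For every stringency threshold of the ladder, the fraction of emitted
#' candidates whose oracle K_D meets the threshold (K_D <= 2\[T\]).
#'
#' @param trajectories a [WalkTrajectory] or list of them.
#' @param oracle an [AffinityOracle].
#' @param ladder a [StringencyLadder].
#' @return data.frame with concentration, threshold, candidate count and
#'   passing fraction per level.
#' @export
evaluateWalks <- function(trajectories, oracle, ladder) {
  if (is(trajectories, "WalkTrajectory")) trajectories <- list(trajectories)
  cand <- unique(unlist(lapply(trajectories, candidates),
                        use.names = FALSE))
  thr <- kdThresholds(ladder)
  if (length(cand) == 0L) {
    return(data.frame(concentration = concentrations(ladder),
                      threshold = thr, nCandidates = 0L, fraction = 0))
  }
  kd <- kdOf(oracle, cand)
  data.frame(concentration = concentrations(ladder), threshold = thr,
             nCandidates = length(cand),
             fraction = vapply(thr, function(t) mean(kd <= t), numeric(1)))
}
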