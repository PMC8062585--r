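# shared fixtures, built in code

A40 <- strrep("A", 40)

# exactly-d substitution mutant (never re-inserts the original base)
mutateExact <- function(sequence, d) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  pos <- sample.int(length(chars), d)
  for (p in pos) {
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1L)
  }
  paste0(chars, collapse = "")
}

# planted mutant families: nBase random 40-mers, each with `size` mutants
# at <= maxD substitutions, interleaved with `nNoise` unrelated sequences
plantedFamilies <- function(nBase = 20L, size = 3L, maxD = 5L,
                            nNoise = 50L, seed = 1L) {
  set.seed(seed)
  base <- randomSequences(nBase)
  fams <- unlist(lapply(base, function(b) {
    c(b, vapply(seq_len(size), function(i) {
      mutateExact(b, sample.int(maxD, 1L))
    }, character(1)))
  }))
  unique(c(fams, randomSequences(nNoise)))
}

# brute-force O(n^2) Levenshtein graph clustering via union-find,
# independent of the package's candidate/verify/components path
bruteClusters <- function(sequences, maxEdit = 5L) {
  n <- length(sequences)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  D <- utils::adist(sequences)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      if (D[i, j] <= maxEdit) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  as.integer(match(roots, unique(roots)))
}

# brute-force AUC over all (positive, negative) pairs
bruteAuc <- function(scores, positive) {
  pos <- scores[positive]
  neg <- scores[!positive]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# tiny hand-built PoolSet: counts matrix + pool metadata
makePoolSet <- function(counts, round = 1L, concentration, polarity,
                        expectedCoverage) {
  info <- data.frame(pool = colnames(counts), round = round,
                     concentration = concentration, polarity = polarity,
                     totalReads = colSums(counts),
                     expectedCoverage = expectedCoverage)
  rownames(info) <- info$pool
  methods::new("PoolSet", SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    colData = S4Vectors::DataFrame(info)))
}

# hand-built StringencyLabels (columns weakest -> strongest)
makeLabels <- function(labels, concentrations) {
  if (is.null(rownames(labels))) {
    rownames(labels) <- paste0("s", seq_len(nrow(labels)))
  }
  methods::new("StringencyLabels", labels = labels,
               concentrations = concentrations)
}

# one small simulated screen reused across tests (built once per run)
.fixtures <- new.env()
smallSim <- function() {
  if (is.null(.fixtures$sim)) {
    .fixtures$sim <- suppressWarnings(
      simulateExperiment(nSequences = 400, seed = 101))
  }
  .fixtures$sim
}
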