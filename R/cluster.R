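#' 6-mer signature vectors for candidate-neighbor search
#'
#' Sparse counts of all k-mers (default k = 6, 4096 dimensions) per
#' sequence. Signature entries of a length-L sequence sum to L - k + 1.
#'
#' @param sequences character vector of DNA sequences (length >= k).
#' @param k k-mer width (default 6).
#' @return a sparse [Matrix::dgCMatrix], sequences x 4^k.
#' @export
kmerSignature <- function(sequences, k = 6L) {
  .checkDNA(sequences)
  if (any(nchar(sequences) < k)) {
    stop("all sequences must be at least ", k, " nt for a ", k,
         "-mer signature")
  }
  x <- Biostrings::DNAStringSet(sequences)
  chunk <- 5000L
  parts <- lapply(split(seq_along(x), ceiling(seq_along(x) / chunk)),
                  function(ii) {
                    Matrix::Matrix(Biostrings::oligonucleotideFrequency(
                      x[ii], width = k), sparse = TRUE)
                  })
  sig <- do.call(rbind, parts)
  rownames(sig) <- NULL
  sig
}

# L2-normalize signature rows
.normalizeRows <- function(sig) {
  nrm <- sqrt(Matrix::rowSums(sig^2))
  nrm[nrm == 0] <- 1
  Matrix::Diagonal(x = 1 / nrm) %*% sig
}

#' Candidate neighbor pairs via an inverted k-mer index
#'
#' Returns every pair of sequences that shares at least one k-mer and
#' whose signature cosine distance is at most `cosineDistanceMax`. The
#' sparse cross-product realizes the inverted index: pairs sharing no
#' k-mer have similarity exactly zero and are never materialized. The
#' default threshold of 0.9 is deliberately loose so the candidate set is
#' a superset of all pairs within Levenshtein distance 5 (verification
#' prunes the rest); see the package vignette for the margin measurement.
#'
#' @param signatures sparse signature matrix from [kmerSignature()].
#' @param cosineDistanceMax maximum cosine distance (1 - cosine
#'   similarity) for a candidate pair, in (0, 1); default 0.9.
#' @return data.frame with integer columns `i`, `j` (i < j, row indices
#'   into `signatures`) and `cosineDist`.
#' @export
candidateNeighbors <- function(signatures, cosineDistanceMax = 0.9) {
  stopifnot(cosineDistanceMax > 0, cosineDistanceMax < 1)
  nrm <- .normalizeRows(signatures)
  sim <- Matrix::tcrossprod(nrm)
  tri <- Matrix::summary(sim)
  keep <- tri$i < tri$j & tri$x >= (1 - cosineDistanceMax) - 1e-12
  data.frame(i = tri$i[keep], j = tri$j[keep],
             cosineDist = pmax(0, 1 - tri$x[keep]))
}

# candidates of `query` rows against `ref` rows (projection phase)
.candidateNeighborsCross <- function(querySig, refSig,
                                     cosineDistanceMax = 0.9) {
  sim <- Matrix::tcrossprod(.normalizeRows(querySig),
                            .normalizeRows(refSig))
  tri <- Matrix::summary(sim)
  keep <- tri$x >= (1 - cosineDistanceMax) - 1e-12
  data.frame(query = tri$i[keep], ref = tri$j[keep],
             cosineDist = pmax(0, 1 - tri$x[keep]))
}

#' Verify candidate pairs by explicit Levenshtein distance
#'
#' @param sequences character vector indexed by the candidate pair table.
#' @param pairs data.frame with columns `i`, `j` from
#'   [candidateNeighbors()].
#' @param maxEdit maximum edit distance kept (default 5, inclusive).
#' @return `pairs` filtered to true neighbors, with an added `dist`
#'   column.
#' @export
verifyNeighbors <- function(sequences, pairs, maxEdit = 5L) {
  stopifnot(maxEdit >= 0)
  if (nrow(pairs) == 0L) {
    return(cbind(pairs, dist = integer(0)))
  }
  d <- levenshtein(sequences[pairs$i], sequences[pairs$j])
  out <- pairs[d <= maxEdit, , drop = FALSE]
  out$dist <- d[d <= maxEdit]
  rownames(out) <- NULL
  out
}

#' Connected components of a neighbor graph
#'
#' Assigns one cluster id per connected component; isolated nodes become
#' singleton clusters. Ids are dense (1..k) in order of first appearance.
#'
#' @param nNodes number of nodes (sequences).
#' @param edges data.frame with columns `i`, `j` (1-based node indices).
#' @return integer vector of cluster ids, length `nNodes`.
#' @export
connectedComponents <- function(nNodes, edges) {
  g <- igraph::make_empty_graph(n = nNodes, directed = FALSE)
  if (nrow(edges)) {
    g <- igraph::add_edges(g, rbind(edges$i, edges$j))
  }
  memb <- igraph::components(g)$membership
  # renumber densely by first appearance
  as.integer(match(memb, unique(memb)))
}

# representative per cluster: maximal summed count, ties lexicographic
.clusterRepresentatives <- function(sequences, clusterIds, totalCounts) {
  ord <- order(clusterIds, -totalCounts, sequences)
  firsts <- ord[!duplicated(clusterIds[ord])]
  reps <- sequences[firsts]
  reps[order(clusterIds[firsts])]
}

#' Cluster sequences by Levenshtein distance (all-pairs graph)
#'
#' The exact graph algorithm: candidate pairs from the 6-mer inverted
#' index, verified by explicit Levenshtein distance <= `maxEdit`, then
#' connected components. Each cluster's representative is its
#' highest-count member (ties broken lexicographically).
#'
#' @param sequences unique character vector of sequences.
#' @param totalCounts summed read count per sequence across all pools
#'   (default all 1).
#' @param maxEdit edge threshold (default 5, inclusive).
#' @param cosineDistanceMax candidate-stage threshold (default 0.9).
#' @return a [ClusterAssignment].
#' @export
clusterSequences <- function(sequences, totalCounts = NULL, maxEdit = 5L,
                             cosineDistanceMax = 0.9) {
  stopifnot(!anyDuplicated(sequences))
  if (is.null(totalCounts)) totalCounts <- rep(1, length(sequences))
  if (length(sequences) == 0L) {
    return(new("ClusterAssignment", sequence = character(0),
               cluster = integer(0), phase = character(0),
               representative = character(0)))
  }
  sig <- kmerSignature(sequences)
  cand <- candidateNeighbors(sig, cosineDistanceMax)
  edges <- verifyNeighbors(sequences, cand, maxEdit)
  ids <- connectedComponents(length(sequences), edges)
  new("ClusterAssignment", sequence = sequences, cluster = ids,
      phase = rep("all_pairs", length(sequences)),
      representative = .clusterRepresentatives(sequences, ids, totalCounts))
}

#' Cluster a count table with an all-pairs/projection split
#'
#' Scalable two-phase clustering. Multi-read sequences (summed count
#' across all pools > 1) fill the all-pairs subset, padded with
#' singleton-count sequences up to `allPairsCap`; that subset is clustered
#' exactly. Every remaining sequence is projected onto its nearest
#' all-pairs cluster if it has a verified neighbor there (smaller
#' Levenshtein distance wins; ties go to the smaller cluster id), and
#' otherwise becomes a new singleton cluster.
#'
#' @param counts a [PoolSet], or a named numeric vector of summed counts
#'   per sequence.
#' @param allPairsCap maximum size of the all-pairs subset (default 1e5).
#' @param maxEdit,cosineDistanceMax as in [clusterSequences()].
#' @return a [ClusterAssignment] covering every input sequence.
#' @export
clusterWithProjection <- function(counts, allPairsCap = 1e5L,
                                  maxEdit = 5L, cosineDistanceMax = 0.9) {
  stopifnot(allPairsCap >= 1)
  if (is(counts, "PoolSet")) {
    totals <- rowSums(poolCounts(counts))
  } else {
    totals <- counts
  }
  sequences <- names(totals)
  stopifnot(!is.null(sequences), !anyDuplicated(sequences))
  n <- length(sequences)

  multi <- which(totals > 1)
  single <- which(totals <= 1)
  if (length(multi) > allPairsCap) {
    # keep the highest-count multi-read sequences within the cap
    multi <- multi[order(-totals[multi], sequences[multi])][seq_len(allPairsCap)]
  }
  pad <- allPairsCap - length(multi)
  apIdx <- sort(c(multi, head(single, max(0L, pad))))
  prIdx <- setdiff(seq_len(n), apIdx)

  ap <- clusterSequences(sequences[apIdx], totals[apIdx], maxEdit,
                         cosineDistanceMax)
  ids <- integer(n)
  ids[apIdx] <- ap@cluster
  phase <- rep("all_pairs", n)
  nextId <- max(ap@cluster, 0L)

  if (length(prIdx)) {
    phase[prIdx] <- "projected"
    refSig <- kmerSignature(sequences[apIdx])
    qSig <- kmerSignature(sequences[prIdx])
    cand <- .candidateNeighborsCross(qSig, refSig, cosineDistanceMax)
    if (nrow(cand)) {
      d <- levenshtein(sequences[prIdx][cand$query],
                       sequences[apIdx][cand$ref])
      cand <- cand[d <= maxEdit, , drop = FALSE]
      cand$dist <- d[d <= maxEdit]
      cand$cluster <- ap@cluster[cand$ref]
    } else {
      cand$dist <- integer(0)
      cand$cluster <- integer(0)
    }
    for (qi in seq_along(prIdx)) {
      hits <- cand[cand$query == qi, , drop = FALSE]
      if (nrow(hits)) {
        best <- hits[order(hits$dist, hits$cluster), , drop = FALSE][1L, ]
        ids[prIdx[qi]] <- best$cluster
      } else {
        nextId <- nextId + 1L
        ids[prIdx[qi]] <- nextId
      }
    }
  }
  # densify ids preserving all-pairs ordering
  ids <- as.integer(match(ids, unique(ids[order(seq_len(n))])))
  new("ClusterAssignment", sequence = sequences, cluster = ids,
      phase = phase,
      representative = .clusterRepresentatives(sequences, ids, totals))
}

#' @rdname sequences
#' @export
setMethod("sequences", "ClusterAssignment", function(object) object@sequence)

#' @rdname clusterIds
#' @export
setMethod("clusterIds", "ClusterAssignment", function(object) {
  setNames(object@cluster, object@sequence)
})

#' @rdname representatives
#' @export
setMethod("representatives", "ClusterAssignment", function(object) {
  object@representative
})

setMethod("show", "ClusterAssignment", function(object) {
  cat("ClusterAssignment:", length(object@sequence), "sequences in",
      length(object@representative), "clusters (",
      sum(object@phase == "projected"), "projected )\n")
})
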