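#' Embed a core subsequence in a homopolymer background
#'
#' Places `core` at 0-based start index `start` inside a
#' `totalLength`-nt frame whose prefix and suffix consist entirely of
#' `backgroundBase`.
#'
#' @param core the subsequence.
#' @param start 0-based start index, `0 <= start <= totalLength -
#'   nchar(core)`.
#' @param backgroundBase one of "A", "C", "G", "T".
#' @param totalLength frame length (default 40).
#' @return a single sequence of length `totalLength`.
#' @examples
#' embedCore("TGG", 0, "A") # "TGG" followed by 37 A's
#' @export
embedCore <- function(core, start, backgroundBase, totalLength = 40L) {
  l <- nchar(core)
  stopifnot(backgroundBase %in% DNA_BASES)
  if (start < 0L || start > totalLength - l) {
    stop("start must lie in [0, ", totalLength - l, "] for a ", l,
         "-nt core")
  }
  paste0(strrep(backgroundBase, start), core,
         strrep(backgroundBase, totalLength - l - start))
}

#' Scan all core subsequences of a full-length aptamer
#'
#' For every subsequence of each requested length, embeds it at every
#' admissible position in all four homopolymer backgrounds — 4 * (L - l
#' + 1) variants per core of length l — scores each variant with
#' `scorer`, and records the score distribution with its median and
#' population variance.
#'
#' @param fullSequence the full-length (40-nt) aptamer.
#' @param scorer function(character) -> numeric model scores.
#' @param lengths core lengths to scan (default c(15, 19, 23, 27, 31,
#'   35, 39)); all must be >= `minLength`.
#' @param minLength smallest admissible core (default 15).
#' @return list of [CoreScan] objects.
#' @export
scanCores <- function(fullSequence, scorer,
                      lengths = c(15L, 19L, 23L, 27L, 31L, 35L, 39L),
                      minLength = 15L) {
  L <- nchar(fullSequence)
  lengths <- sort(unique(as.integer(lengths)))
  stopifnot(all(lengths >= minLength), all(lengths <= L))
  scans <- list()
  for (l in lengths) {
    cores <- unique(substring(fullSequence, 1:(L - l + 1), l:L))
    nPos <- L - l + 1L
    # batch all embeddings of this length into one scorer call
    embeds <- character(0)
    for (core in cores) {
      for (bg in DNA_BASES) {
        embeds <- c(embeds, vapply(0:(nPos - 1L), embedCore,
                                   character(1), core = core,
                                   backgroundBase = bg, totalLength = L))
      }
    }
    scores <- scorer(embeds)
    k <- 0L
    for (core in cores) {
      m <- matrix(scores[k + seq_len(4L * nPos)], nrow = 4L,
                  byrow = TRUE,
                  dimnames = list(DNA_BASES, 0:(nPos - 1L)))
      k <- k + 4L * nPos
      scans[[length(scans) + 1L]] <- new(
        "CoreScan", core = core, frameLength = L, scores = m,
        median = stats::median(m),
        variance = mean((m - mean(m))^2))
    }
  }
  scans
}

#' Rank scanned cores by a distribution statistic
#'
#' `max_median` favors cores that score high across embeddings;
#' `min_variance` favors position/background-robust cores; `min_median`
#' is the sanity mode for deliberately weak picks. Ties are broken by
#' core length ascending, then lexicographically.
#'
#' @param scans list of [CoreScan] from [scanCores()].
#' @param mode `"max_median"` (default), `"min_variance"` or
#'   `"min_median"`.
#' @return data.frame of cores with length, median, variance and rank,
#'   best first.
#' @export
rankCores <- function(scans, mode = c("max_median", "min_variance",
                                      "min_median")) {
  mode <- match.arg(mode)
  df <- data.frame(
    core = vapply(scans, function(s) s@core, character(1)),
    length = vapply(scans, function(s) nchar(s@core), integer(1)),
    median = vapply(scans, function(s) s@median, numeric(1)),
    variance = vapply(scans, function(s) s@variance, numeric(1)))
  ord <- switch(mode,
    max_median = order(-df$median, df$length, df$core),
    min_variance = order(df$variance, df$length, df$core),
    min_median = order(df$median, df$length, df$core))
  out <- df[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

setMethod("show", "CoreScan", function(object) {
  cat("CoreScan: ", object@core, " (", nchar(object@core), " nt in ",
      object@frameLength, "-nt frame)\n", sep = "")
  cat("  ", length(object@scores), " embeddings; median ",
      signif(object@median, 4), ", variance ",
      signif(object@variance, 4), "\n", sep = "")
})

# overlapping-occurrence and presence counts of all k-mers in a sequence set
.kmerPresence <- function(sequences, k) {
  x <- Biostrings::DNAStringSet(sequences)
  counts <- Biostrings::oligonucleotideFrequency(x, width = k)
  list(presence = colSums(counts > 0), occurrences = colSums(counts),
       nOcc = sum(counts))
}

#' Differential k-mer enrichment between sequence sets
#'
#' A direct substitute for PWM/EM motif discovery: for every k in
#' `kRange`, computes per-k-mer log-odds of occurrence frequency in the
#' positive set versus the background set (pseudocount 1), and a
#' one-sided Fisher exact test on per-sequence presence/absence,
#' Bonferroni-corrected over all 4^k k-mers of that length. The reported
#' consensus is the k-mer with the smallest corrected p-value across the
#' screened k (log-odds breaks ties), which fixes the consensus length at
#' the most significant k.
#'
#' @param positives character vector of positive-set sequences.
#' @param background character vector of background sequences.
#' @param kRange k-mer lengths screened (default 4:8).
#' @param alpha significance level applied after Bonferroni correction
#'   (default 0.05).
#' @return data.frame of enriched k-mers (kmer, k, presence counts,
#'   log-odds, p, corrected p), sorted by corrected p; attributes
#'   `consensus` (character, `NA` if nothing survives correction) and
#'   `consensusK`.
#' @export
differentialKmerEnrichment <- function(positives, background,
                                       kRange = 4:8, alpha = 0.05) {
  stopifnot(length(positives) > 0, length(background) > 0)
  nPos <- length(positives)
  nBg <- length(background)
  perK <- list()
  for (k in kRange) {
    pos <- .kmerPresence(positives, k)
    bg <- .kmerPresence(background, k)
    seen <- pos$presence > 0 | bg$presence > 0
    kmers <- names(pos$presence)[seen]
    a <- pos$presence[seen] # positive sequences containing the k-mer
    b <- bg$presence[seen]
    # one-sided Fisher exact (enrichment) = hypergeometric tail
    p <- phyper(a - 1, nPos, nBg, a + b, lower.tail = FALSE)
    logOdds <- log((pos$occurrences[seen] + 1) / (pos$nOcc + 4^k)) -
      log((bg$occurrences[seen] + 1) / (bg$nOcc + 4^k))
    perK[[as.character(k)]] <- data.frame(
      kmer = kmers, k = k, posPresent = as.integer(a),
      bgPresent = as.integer(b), nPos = nPos, nBg = nBg,
      logOdds = unname(logOdds), p = unname(p),
      pBonferroni = pmin(1, unname(p) * 4^k))
  }
  tab <- do.call(rbind, perK)
  tab <- tab[order(tab$pBonferroni, -tab$logOdds, tab$kmer), ,
             drop = FALSE]
  rownames(tab) <- NULL
  hits <- tab[tab$pBonferroni <= alpha, , drop = FALSE]
  if (nrow(hits)) {
    # consensus = the most significant k-mer overall (its k is the k
    # maximizing significance); pseudocount log-odds breaks exact ties
    attr(tab, "consensus") <- hits$kmer[1L]
    attr(tab, "consensusK") <- hits$k[1L]
  } else {
    attr(tab, "consensus") <- NA_character_
    attr(tab, "consensusK") <- NA_integer_
  }
  tab
}
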