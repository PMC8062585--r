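#' Construct a ground-truth affinity oracle
#'
#' The oracle stands in for the unknown true fitness landscape of a
#' screening library: it deterministically maps any DNA sequence to a
#' dissociation constant. The default landscape has a weak 10 uM baseline
#' and a single planted 7-nt core motif (`TGGATAG`) conferring a 100-fold
#' affinity improvement, with mild lognormal sequence-level noise
#' (sdlog = 0.5) so affinities are graded rather than binary. Noise is
#' hashed from the sequence itself, so repeated queries agree.
#'
#' @param baselineKd baseline K_D in nM (default 10000 = 10 uM).
#' @param motifs character vector of planted core motifs.
#' @param motifFold fold-improvement per motif (K_D divisor), recycled to
#'   `length(motifs)`.
#' @param kmerWeights optional named numeric vector: log10 K_D added per
#'   occurrence of each named k-mer (default none).
#' @param noiseSdLog sdlog of multiplicative lognormal noise (0 = none).
#' @param seed integer oracle seed.
#' @return an [AffinityOracle].
#' @examples
#' orc <- affinityOracle(seed = 1)
#' kdOf(orc, c(paste(rep("A", 40), collapse = ""),
#'             paste0("TGGATAG", paste(rep("A", 33), collapse = ""))))
#' @export
affinityOracle <- function(baselineKd = 10000, motifs = "TGGATAG",
                           motifFold = 100, kmerWeights = numeric(0),
                           noiseSdLog = 0.5, seed = 1L) {
  motifFold <- rep_len(motifFold, length(motifs))
  new("AffinityOracle", baselineKd = as.numeric(baselineKd),
      motifs = as.character(motifs), motifFold = as.numeric(motifFold),
      kmerWeights = kmerWeights, noiseSdLog = as.numeric(noiseSdLog),
      seed = as.integer(seed))
}

#' @rdname kdOf
#' @export
setMethod("kdOf", "AffinityOracle", function(object, sequences) {
  if (length(sequences) == 0L) return(numeric(0))
  .checkDNA(sequences)
  log10kd <- rep(log10(object@baselineKd), length(sequences))
  for (i in seq_along(object@motifs)) {
    hit <- grepl(object@motifs[i], sequences, fixed = TRUE)
    log10kd[hit] <- log10kd[hit] - log10(object@motifFold[i])
  }
  if (length(object@kmerWeights)) {
    kmers <- names(object@kmerWeights)
    for (i in seq_along(kmers)) {
      # overlapping occurrence count via fixed-pattern sliding match
      occ <- vapply(sequences, function(s) {
        L <- nchar(s); k <- nchar(kmers[i])
        if (L < k) return(0L)
        sum(substring(s, 1:(L - k + 1), k:L) == kmers[i])
      }, integer(1), USE.NAMES = FALSE)
      log10kd <- log10kd + occ * unname(object@kmerWeights[i])
    }
  }
  if (object@noiseSdLog > 0) {
    # one reproducible draw per (oracle seed, sequence)
    noise <- vapply(.stringHash(sequences), function(h) {
      set.seed(as.integer((as.double(h) + as.double(object@seed) * 97) %%
                            2147483647))
      rnorm(1)
    }, numeric(1))
    log10kd <- log10kd + noise * object@noiseSdLog / log(10)
  }
  10^log10kd
})

setMethod("show", "AffinityOracle", function(object) {
  cat("AffinityOracle\n")
  cat("  baseline K_D:", object@baselineKd, "nM\n")
  if (length(object@motifs)) {
    cat("  planted motifs:",
        paste(sprintf("%s (%gx)", object@motifs, object@motifFold),
              collapse = ", "), "\n")
  }
  cat("  lognormal noise sdlog:", object@noiseSdLog,
      " seed:", object@seed, "\n")
})
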