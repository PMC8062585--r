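#' One-hot encode fixed-length DNA sequences
#'
#' Each position contributes 4 binary slots in fixed base order A, C, G, T;
#' a length-40 sequence yields 160 values with exactly one 1 per position
#' block.
#'
#' @param sequences character vector of equal-length sequences over
#'   A/C/G/T (default frame length 40).
#' @param length expected sequence length (default 40).
#' @return numeric matrix, `length(sequences)` x `4 * length`.
#' @export
oneHot <- function(sequences, length = 40L) {
  .checkDNA(sequences, len = length)
  n <- base::length(sequences)
  cm <- .seqCharMatrix(sequences)
  baseIdx <- match(cm, DNA_BASES)
  out <- matrix(0, nrow = n, ncol = 4L * length)
  pos <- col(cm)
  out[cbind(rep(seq_len(n), times = length),
            (as.vector(pos) - 1L) * 4L + as.vector(baseIdx))] <- 1
  colnames(out) <- paste0("pos", rep(seq_len(length), each = 4L), "_",
                          rep(DNA_BASES, length))
  out
}

#' Overlapping k-mer count features (k = 1..kmax)
#'
#' Counts every k-mer of each length up to `kmax` in fixed lexicographic
#' order (A < C < G < T). For k = 1..4 the blocks have 4 + 16 + 64 + 256 =
#' 340 dimensions, and a length-40 sequence has per-k totals 40, 39, 38,
#' 37 (154 in all).
#'
#' @param sequences character vector of DNA sequences.
#' @param kmax largest k (default 4).
#' @return numeric matrix, `length(sequences)` x `sum(4^(1:kmax))`.
#' @export
kmerCountFeatures <- function(sequences, kmax = 4L) {
  .checkDNA(sequences)
  x <- Biostrings::DNAStringSet(sequences)
  blocks <- lapply(seq_len(kmax), function(k) {
    Biostrings::oligonucleotideFrequency(x, width = k)
  })
  out <- do.call(cbind, blocks)
  storage.mode(out) <- "double"
  rownames(out) <- NULL
  out
}

#' Combined model input encoding
#'
#' Concatenates the one-hot block (4 x 40 = 160 values) with overlapping
#' k-mer counts for k = 1..4 (340 values) into the 500-dimensional model
#' input vector.
#'
#' @param sequences character vector of length-40 sequences.
#' @return numeric matrix, `length(sequences)` x 500.
#' @examples
#' dim(encodeSequences(randomSequences(3))) # 3 x 500
#' @export
encodeSequences <- function(sequences) {
  cbind(oneHot(sequences, 40L), kmerCountFeatures(sequences, 4L))
}
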