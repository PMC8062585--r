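#' @importFrom methods new is slot validObject setValidity show
#' @importFrom stats median rnorm runif rmultinom var quantile p.adjust
#'   phyper setNames rbinom wilcox.test cor pnorm sd coef
#' @importFrom utils adist head
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Derive an independent RNG sub-stream seed
#'
#' A single experiment-level seed fans out into per-stage streams so that
#' stages can be re-run independently yet reproducibly. The derivation is a
#' fixed integer hash of the parent seed and a stage tag; results stay below
#' 2^31.
#'
#' @param seed integer parent seed.
#' @param tag character stage tag (e.g. `"sort"`, `"sequencing"`).
#' @return a single integer usable with [set.seed()].
#' @export
deriveSeed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- as.double(seed) %% 2147483647
  for (code in utf8ToInt(as.character(tag))) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer(h)
}

# Deterministic per-string hash (poly-rolling, mod 2^31 - 1). Used to give
# every sequence its own reproducible noise draw in the affinity oracle.
.stringHash <- function(x) {
  vapply(x, function(s) {
    h <- 7
    for (code in utf8ToInt(s)) h <- (h * 131 + code) %% 2147483647
    as.integer(h)
  }, integer(1), USE.NAMES = FALSE)
}

#' Generate uniform random DNA sequences
#'
#' @param n number of sequences.
#' @param length sequence length in nt (default 40, the variable-region
#'   length of the screened library).
#' @return character vector of `n` sequences over A/C/G/T.
#' @export
randomSequences <- function(n, length = 40L) {
  if (n == 0L) return(character(0))
  m <- matrix(sample(DNA_BASES, n * length, replace = TRUE), nrow = n)
  apply(m, 1L, paste0, collapse = "")
}

.checkDNA <- function(x, len = NULL) {
  if (any(grepl("[^ACGT]", x))) {
    stop("sequences must contain only A, C, G, T")
  }
  if (!is.null(len) && any(nchar(x) != len)) {
    stop("sequences must have length ", len)
  }
  invisible(x)
}

# character vector -> n x L matrix of single characters
.seqCharMatrix <- function(x) {
  L <- unique(nchar(x))
  if (length(L) != 1L) stop("sequences must share one length")
  matrix(unlist(strsplit(x, "", fixed = TRUE), use.names = FALSE),
         ncol = L, byrow = TRUE)
}

#' Levenshtein distance between sequence pairs
#'
#' Thin wrapper over [utils::adist()] (unit-cost insert/delete/substitute).
#'
#' @param a,b character vectors of equal length; distances are computed
#'   element-wise.
#' @return integer vector of edit distances.
#' @export
levenshtein <- function(a, b) {
  stopifnot(length(a) == length(b))
  if (length(a) == 0L) return(integer(0))
  vapply(seq_along(a), function(i) as.integer(adist(a[i], b[i])[1L, 1L]),
         integer(1))
}
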