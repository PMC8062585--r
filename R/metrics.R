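#' Rank-based AUC (Mann-Whitney, ties averaged)
#'
#' @param scores numeric predictions.
#' @param positive logical relevance per element.
#' @return AUC in \[0, 1\].
#' @export
rankAuc <- function(scores, positive) {
  stopifnot(length(scores) == length(positive))
  n1 <- sum(positive)
  n0 <- sum(!positive)
  if (n1 == 0L || n0 == 0L) {
    stop("AUC undefined: need at least one positive and one negative")
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' AUC over the top fraction of non-zero reference values
#'
#' Model-ranking metric: relevance is membership in the top
#' `topFraction` of the non-zero reference values (e.g. summed
#' high-stringency pool counts) in the test set, and the AUC of the model
#' scores is computed against that binary relevance over the non-zero
#' reference subset.
#'
#' @param scores model scores.
#' @param reference numeric reference values (same length).
#' @param topFraction fraction defining relevance (default 0.01).
#' @return AUC.
#' @export
aucTopFraction <- function(scores, reference, topFraction = 0.01) {
  stopifnot(length(scores) == length(reference),
            topFraction > 0, topFraction <= 1)
  keep <- reference != 0
  if (sum(keep) < 2L) stop("need at least two non-zero reference values")
  s <- scores[keep]
  ref <- reference[keep]
  k <- ceiling(topFraction * length(ref))
  relevant <- seq_along(ref) %in% order(-ref)[seq_len(k)]
  if (all(relevant)) stop("topFraction covers every non-zero value")
  rankAuc(s, relevant)
}

#' AUC against a stringency-threshold label
#'
#' Positives are the concordant positive sequences at the requested
#' stringency level (positive there and at every weaker level); negatives
#' are the rest of the evaluated set.
#'
#' @param scores named or ordered model scores for the evaluated
#'   sequences.
#' @param labels a [StringencyLabels] covering the same sequences (in the
#'   same order if `scores` is unnamed).
#' @param level stringency level index (1 = weakest) or concentration in
#'   nM.
#' @return AUC.
#' @export
stringencyAuc <- function(scores, labels, level = 1L) {
  lab <- labelMatrix(labels)
  if (!is.null(names(scores))) {
    lab <- lab[names(scores), , drop = FALSE]
  }
  stopifnot(length(scores) == nrow(lab))
  if (level > ncol(lab)) { # passed as a concentration in nM
    level <- match(level, concentrations(labels))
    if (is.na(level)) stop("level matches no stringency of the labels")
  }
  isPos <- lab[, seq_len(level), drop = FALSE] == "positive"
  positive <- rowSums(isPos) == level
  rankAuc(scores, positive)
}
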