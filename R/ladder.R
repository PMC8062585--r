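#' Construct a stringency ladder
#'
#' Target concentrations are ordered weakest stringency first (largest
#' concentration). With the FACS gate at F_max/3, a sort at concentration
#' \[T\] collects aptamers with K_D <= 2\[T\], so each level's derived
#' affinity threshold is twice its concentration. The default ladder is the
#' four-level fourfold design (4, 16, 64, 256 nM; thresholds 8, 32, 128,
#' 512 nM).
#'
#' @param concentrations numeric, nM, strictly decreasing (weakest first);
#'   consecutive ratios must equal `foldFactor`.
#' @param foldFactor ratio between consecutive levels (default 4).
#' @param gateFraction FACS gate as a fraction of F_max (default 1/3).
#' @param coverage expected bead coverage per pool: expected sequencing
#'   reads per bead-sequence present in a pool (default 50).
#' @return a [StringencyLadder].
#' @examples
#' ladder <- stringencyLadder()
#' kdThresholds(ladder) # 512 128 32 8
#' @export
stringencyLadder <- function(concentrations = c(256, 64, 16, 4),
                             foldFactor = 4, gateFraction = 1 / 3,
                             coverage = 50) {
  new("StringencyLadder", concentrations = as.numeric(concentrations),
      foldFactor = as.numeric(foldFactor),
      gateFraction = as.numeric(gateFraction),
      coverage = as.numeric(coverage))
}

#' @rdname kdThresholds
#' @export
setMethod("kdThresholds", "StringencyLadder", function(object) {
  kdThresholdForConcentration(object@concentrations)
})

#' @rdname concentrations
#' @export
setMethod("concentrations", "StringencyLadder", function(object) {
  object@concentrations
})

#' Gate fraction of a ladder
#' @param object a [StringencyLadder].
#' @return numeric(1).
#' @export
gateFraction <- function(object) object@gateFraction

#' Expected bead coverage of a ladder
#' @param object a [StringencyLadder].
#' @return numeric(1), expected reads per bead-sequence per pool.
#' @export
expectedCoverage <- function(object) object@coverage

setMethod("show", "StringencyLadder", function(object) {
  cat("StringencyLadder:", length(object@concentrations), "levels\n")
  cat("  [T] (nM):       ", paste(object@concentrations, collapse = ", "),
      "\n")
  cat("  K_D thresholds: ", paste(kdThresholds(object), collapse = ", "),
      "nM\n")
  cat("  gate: F_max *", format(object@gateFraction, digits = 4),
      "; coverage:", object@coverage, "reads/sequence\n")
})
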