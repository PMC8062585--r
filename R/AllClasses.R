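#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' AffinityOracle: ground-truth sequence -> K_D map
#'
#' Rule-based dissociation-constant oracle used by the particle-display
#' simulator. A sequence starts at a baseline K_D (nM) which is divided by a
#' multiplicative bonus for every planted core motif it contains, optionally
#' shifted by per-k-mer log-additive weights, and multiplied by seeded
#' lognormal noise. Noise is a deterministic function of (oracle seed,
#' sequence), so the oracle is a fixed landscape: the same sequence always
#' maps to the same K_D.
#'
#' @slot baselineKd numeric(1), baseline K_D in nM (> 0).
#' @slot motifs character, planted core motifs.
#' @slot motifFold numeric, per-motif fold-improvement (K_D divisor), same
#'   length as `motifs`.
#' @slot kmerWeights named numeric, optional log10-additive K_D weights per
#'   k-mer occurrence (empty by default).
#' @slot noiseSdLog numeric(1), sdlog of the lognormal noise (0 disables).
#' @slot seed integer(1), oracle seed.
#' @export
setClass("AffinityOracle", representation(
  baselineKd = "numeric",
  motifs = "character",
  motifFold = "numeric",
  kmerWeights = "numeric",
  noiseSdLog = "numeric",
  seed = "integer"
))

setValidity("AffinityOracle", function(object) {
  msg <- character(0)
  if (length(object@baselineKd) != 1L || object@baselineKd <= 0)
    msg <- c(msg, "baselineKd must be a single positive number")
  if (length(object@motifs) != length(object@motifFold))
    msg <- c(msg, "motifs and motifFold must have equal length")
  if (any(object@motifFold <= 0))
    msg <- c(msg, "motifFold entries must be positive")
  if (length(object@noiseSdLog) != 1L || object@noiseSdLog < 0)
    msg <- c(msg, "noiseSdLog must be a single non-negative number")
  if (length(msg)) msg else TRUE
})

#' StringencyLadder: ordered sort concentrations and derived thresholds
#'
#' An ordered ladder of target concentrations \[T\] (nM), strictly
#' decreasing stringency-upward by a common fold factor. With the FACS gate
#' at `gateFraction` of F_max (default 1/3), a sort at \[T\] isolates
#' aptamers with K_D <= 2\[T\], so the derived affinity threshold at each
#' level is exactly 2\[T\].
#'
#' @slot concentrations numeric, target concentrations in nM ordered weakest
#'   (largest) to strongest (smallest) stringency.
#' @slot foldFactor numeric(1), ratio between consecutive concentrations.
#' @slot gateFraction numeric(1), FACS collection gate as a fraction of
#'   F_max (default 1/3).
#' @slot coverage numeric(1), expected bead coverage per pool (expected
#'   sequencing reads per bead-sequence present in the pool).
#' @export
setClass("StringencyLadder", representation(
  concentrations = "numeric",
  foldFactor = "numeric",
  gateFraction = "numeric",
  coverage = "numeric"
))

setValidity("StringencyLadder", function(object) {
  msg <- character(0)
  conc <- object@concentrations
  if (length(conc) < 1L || any(conc <= 0))
    msg <- c(msg, "concentrations must be positive")
  if (length(conc) > 1L) {
    ratios <- conc[-length(conc)] / conc[-1L]
    if (any(abs(ratios - object@foldFactor) > 1e-8 * object@foldFactor))
      msg <- c(msg, "consecutive concentration ratios must equal foldFactor")
  }
  if (object@gateFraction <= 0 || object@gateFraction >= 1)
    msg <- c(msg, "gateFraction must lie in (0, 1)")
  if (length(object@coverage) != 1L || object@coverage <= 0)
    msg <- c(msg, "coverage must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' PoolSet: sequencing counts across screening pools
#'
#' A [SummarizedExperiment::SummarizedExperiment] subclass holding one
#' `counts` assay (sequences x pools, non-negative integers) with pool
#' metadata in `colData`: `round`, `concentration` (nM), `polarity`
#' (`"positive"`/`"negative"`), `totalReads`, `expectedCoverage`.
#'
#' @export
setClass("PoolSet", contains = "SummarizedExperiment")

setValidity("PoolSet", function(object) {
  msg <- character(0)
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "PoolSet requires a 'counts' assay")
  else if (any(SummarizedExperiment::assay(object, "counts") < 0))
    msg <- c(msg, "counts must be non-negative")
  need <- c("round", "concentration", "polarity", "totalReads",
            "expectedCoverage")
  have <- colnames(SummarizedExperiment::colData(object))
  if (!all(need %in% have))
    msg <- c(msg, paste("colData must contain:", paste(need, collapse = ", ")))
  else if (!all(object$polarity %in% c("positive", "negative")))
    msg <- c(msg, "polarity must be 'positive' or 'negative'")
  if (is.null(rownames(object)))
    msg <- c(msg, "rownames (sequences) are required")
  if (length(msg)) msg else TRUE
})

#' SimulatedExperiment: a simulated particle-display screen
#'
#' @slot library data.frame with columns `sequence` and `kd` (true K_D, nM).
#' @slot pools a [PoolSet] of per-round, per-stringency positive/negative
#'   sequencing counts.
#' @slot ladder the [StringencyLadder] used.
#' @slot seed integer(1) experiment seed.
#' @slot params list of simulator parameters (provenance).
#' @export
setClass("SimulatedExperiment", representation(
  library = "data.frame",
  pools = "PoolSet",
  ladder = "StringencyLadder",
  seed = "integer",
  params = "list"
))

setValidity("SimulatedExperiment", function(object) {
  msg <- character(0)
  if (!all(c("sequence", "kd") %in% colnames(object@library)))
    msg <- c(msg, "library needs 'sequence' and 'kd' columns")
  else {
    if (any(object@library$kd <= 0)) msg <- c(msg, "library K_D must be > 0")
    if (!all(rownames(object@pools) %in% object@library$sequence))
      msg <- c(msg, "every pooled sequence must appear in the library")
  }
  if (length(msg)) msg else TRUE
})

#' ClusterAssignment: Levenshtein-linked sequence clusters
#'
#' @slot sequence character, the clustered sequences.
#' @slot cluster integer, cluster id per sequence (1-based, dense).
#' @slot phase character, `"all_pairs"` or `"projected"` per sequence.
#' @slot representative character, one representative per cluster id (the
#'   member with maximal summed count; ties broken lexicographically).
#' @export
setClass("ClusterAssignment", representation(
  sequence = "character",
  cluster = "integer",
  phase = "character",
  representative = "character"
))

setValidity("ClusterAssignment", function(object) {
  msg <- character(0)
  n <- length(object@sequence)
  if (length(object@cluster) != n || length(object@phase) != n)
    msg <- c(msg, "cluster and phase must parallel sequence")
  if (n && anyDuplicated(object@sequence))
    msg <- c(msg, "sequences must be unique")
  if (n) {
    ids <- sort(unique(object@cluster))
    if (!identical(ids, seq_along(ids)))
      msg <- c(msg, "cluster ids must be dense 1..k")
    if (length(object@representative) != length(ids))
      msg <- c(msg, "one representative per cluster required")
    else if (!all(object@representative[object@cluster] %in% object@sequence))
      msg <- c(msg, "representatives must be cluster members")
  }
  if (!all(object@phase %in% c("all_pairs", "projected")))
    msg <- c(msg, "phase must be 'all_pairs' or 'projected'")
  if (length(msg)) msg else TRUE
})

#' StringencyLabels: ternary pool labels per stringency level
#'
#' A sequences x stringency-levels matrix with entries `"positive"`,
#' `"negative"` or `"ambiguous"`; columns are ordered weakest -> strongest
#' stringency and named by concentration.
#'
#' @slot labels character matrix (rownames = sequences).
#' @slot concentrations numeric, per-column target concentration (nM),
#'   decreasing.
#' @export
setClass("StringencyLabels", representation(
  labels = "matrix",
  concentrations = "numeric"
))

setValidity("StringencyLabels", function(object) {
  msg <- character(0)
  if (!all(object@labels %in% c("positive", "negative", "ambiguous")))
    msg <- c(msg, "labels must be positive/negative/ambiguous")
  if (ncol(object@labels) != length(object@concentrations))
    msg <- c(msg, "one concentration per label column required")
  if (length(object@concentrations) > 1L &&
      any(diff(object@concentrations) >= 0))
    msg <- c(msg, "concentrations must decrease (weakest first)")
  if (is.null(rownames(object@labels)))
    msg <- c(msg, "label rownames (sequences) are required")
  if (length(msg)) msg else TRUE
})

#' ModelSpec: architecture and training hyperparameters
#'
#' @slot convFilters integer, filters per convolutional layer (length 0-3);
#'   convolutions run over the one-hot block reshaped to 40 x 4.
#' @slot convWidth integer(1), convolution window width in nt.
#' @slot hidden integer, fully connected hidden layer sizes (length 0-4).
#' @slot activation character(1), `"relu"` or `"tanh"`.
#' @slot dropout numeric(1), dropout probability in hidden layers.
#' @slot head character(1), `"fully_connected"` or `"latent_affinity"`.
#' @slot optimizer character(1), `"sgd"` (momentum SGD) or `"adam"`.
#' @slot learningRate,momentum,batchSize,epochs numeric/integer scalars.
#' @slot upsampleFloor numeric(1), minimum positive fraction per batch.
#' @export
setClass("ModelSpec", representation(
  convFilters = "integer",
  convWidth = "integer",
  hidden = "integer",
  activation = "character",
  dropout = "numeric",
  head = "character",
  optimizer = "character",
  learningRate = "numeric",
  momentum = "numeric",
  batchSize = "integer",
  epochs = "integer",
  upsampleFloor = "numeric"
))

setValidity("ModelSpec", function(object) {
  msg <- character(0)
  if (length(object@convFilters) > 3L)
    msg <- c(msg, "at most 3 convolutional layers are supported")
  if (length(object@hidden) > 4L)
    msg <- c(msg, "at most 4 fully connected layers are supported")
  if (!object@head %in% c("fully_connected", "latent_affinity"))
    msg <- c(msg, "head must be 'fully_connected' or 'latent_affinity'")
  if (!object@optimizer %in% c("sgd", "adam"))
    msg <- c(msg, "optimizer must be 'sgd' or 'adam'")
  if (!object@activation %in% c("relu", "tanh"))
    msg <- c(msg, "activation must be 'relu' or 'tanh'")
  if (object@dropout < 0 || object@dropout >= 1)
    msg <- c(msg, "dropout must lie in [0, 1)")
  if (object@learningRate <= 0) msg <- c(msg, "learningRate must be > 0")
  if (object@upsampleFloor < 0 || object@upsampleFloor > 1)
    msg <- c(msg, "upsampleFloor must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' TrainedAffinityModel: a trained sequence-to-affinity scorer
#'
#' @slot weights list of layer weight matrices/vectors (opaque).
#' @slot spec the [ModelSpec] used.
#' @slot formulation character(1): `"counts"`, `"binned"` or `"superbin"`.
#' @slot targetSchema list describing the output columns (pool names for
#'   Counts, concentrations for Binned, scalar for SuperBin) and, for
#'   Counts, the designated high-stringency positive pools whose predicted
#'   counts sum to the affinity score.
#' @slot targetCenter,targetScale numeric, per-output standardization
#'   applied to targets during optimization (predictions are returned on
#'   the original scale).
#' @slot history data.frame of per-epoch training loss.
#' @export
setClass("TrainedAffinityModel", representation(
  weights = "list",
  spec = "ModelSpec",
  formulation = "character",
  targetSchema = "list",
  targetCenter = "numeric",
  targetScale = "numeric",
  history = "data.frame"
))

#' WalkTrajectory: one seed's mutate-score-select walk
#'
#' @slot seedSequence character(1), the starting sequence.
#' @slot provenance character(1): `"random"`, `"experimental"`,
#'   `"ml_screened"`.
#' @slot guided logical(1), model-guided (TRUE) or random-selection baseline.
#' @slot table data.frame with columns `round`, `parent`, `mutant`, `score`,
#'   `selected` (one row per sampled mutant; round 0 holds the seed).
#' @slot config list of walk parameters.
#' @export
setClass("WalkTrajectory", representation(
  seedSequence = "character",
  provenance = "character",
  guided = "logical",
  table = "data.frame",
  config = "list"
))

setValidity("WalkTrajectory", function(object) {
  msg <- character(0)
  need <- c("round", "parent", "mutant", "score", "selected")
  if (!all(need %in% colnames(object@table)))
    msg <- c(msg, paste("table needs columns:", paste(need, collapse = ", ")))
  if (!object@provenance %in% c("random", "experimental", "ml_screened"))
    msg <- c(msg, "provenance must be random/experimental/ml_screened")
  if (length(msg)) msg else TRUE
})

#' CoreScan: score distribution of one candidate core subsequence
#'
#' Scores of the core embedded at every admissible start index in each of
#' the four homopolymer backgrounds; 4 * (L - l + 1) scores in total for a
#' core of length l scanned within a length-L frame.
#'
#' @slot core character(1) the subsequence.
#' @slot frameLength integer(1), L.
#' @slot scores numeric matrix, 4 x (L - l + 1), rownames A/C/G/T, columns
#'   0-based start indices.
#' @slot median,variance numeric(1) summary statistics (population variance).
#' @export
setClass("CoreScan", representation(
  core = "character",
  frameLength = "integer",
  scores = "matrix",
  median = "numeric",
  variance = "numeric"
))

setValidity("CoreScan", function(object) {
  l <- nchar(object@core)
  L <- object@frameLength
  if (!identical(dim(object@scores), c(4L, L - l + 1L)))
    return("scores must be 4 x (L - l + 1)")
  TRUE
})
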