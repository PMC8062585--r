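#' Ground-truth dissociation constants for sequences
#'
#' @param object an [AffinityOracle].
#' @param sequences character vector of DNA sequences.
#' @return numeric vector of K_D values (nM), one per sequence.
#' @export
setGeneric("kdOf", function(object, sequences) standardGeneric("kdOf"))

#' Derived K_D thresholds of a stringency ladder
#'
#' @param object a [StringencyLadder].
#' @return numeric vector, 2 * \[T\] per level (nM).
#' @export
setGeneric("kdThresholds", function(object) standardGeneric("kdThresholds"))

#' Target concentrations of a stringency ladder
#' @param object a [StringencyLadder].
#' @return numeric vector of concentrations (nM), weakest first.
#' @export
setGeneric("concentrations",
           function(object) standardGeneric("concentrations"))

#' Model affinity score for sequences
#'
#' Reduces a trained model's outputs to one scalar affinity score per
#' sequence: Counts sums the designated final-round high-stringency
#' positive-pool outputs; Binned sums stringency outputs weighted by
#' stringency rank; SuperBin returns the scalar output directly.
#'
#' @param object a [TrainedAffinityModel].
#' @param sequences character vector of length-40 DNA sequences.
#' @return numeric vector of scores (higher = higher predicted affinity).
#' @export
setGeneric("affinityScore",
           function(object, sequences) standardGeneric("affinityScore"))

#' Sequences held by an object
#' @param object a ClusterAssignment, StringencyLabels or
#'   SimulatedExperiment.
#' @return character vector of sequences.
#' @export
setGeneric("sequences", function(object) standardGeneric("sequences"))

#' Cluster ids of a ClusterAssignment
#' @param object a [ClusterAssignment].
#' @return named integer vector (names = sequences).
#' @export
setGeneric("clusterIds", function(object) standardGeneric("clusterIds"))

#' Cluster representatives
#' @param object a [ClusterAssignment].
#' @return character vector, one representative per cluster id.
#' @export
setGeneric("representatives",
           function(object) standardGeneric("representatives"))

#' Ternary label matrix
#' @param object a [StringencyLabels].
#' @return character matrix (sequences x levels).
#' @export
setGeneric("labelMatrix", function(object) standardGeneric("labelMatrix"))

#' Candidate sequences emitted by a walk
#' @param object a [WalkTrajectory].
#' @param ... unused.
#' @return character vector of selected candidate sequences (all rounds).
#' @export
setGeneric("candidates", function(object, ...) standardGeneric("candidates"))
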