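#' Filter reads and extract the variable region
#'
#' Keeps reads that contain the forward primer, an exact-length variable
#' region, and the reverse primer, with no ambiguous base (N) in the
#' region and mean base quality at or above the threshold. All other
#' reads are dropped and tallied by reason.
#'
#' @param reads character vector of read sequences, or a
#'   [Biostrings::QualityScaledDNAStringSet] (as read from FASTQ).
#' @param forwardPrimer,reversePrimer primer sequences flanking the
#'   variable region.
#' @param regionLength required variable-region length (default 40).
#' @param minMeanQuality minimum mean Phred quality (default 20; ignored
#'   when `reads` carries no qualities).
#' @return character vector of extracted variable regions, with a
#'   `rejects` attribute: a named integer tally (`no_primer`,
#'   `bad_length`, `ambiguous_base`, `low_quality`).
#' @export
filterAndExtract <- function(reads, forwardPrimer, reversePrimer,
                             regionLength = 40L, minMeanQuality = 20) {
  if (is(reads, "QualityScaledDNAStringSet")) {
    quals <- methods::as(Biostrings::quality(reads), "IntegerList")
    meanQ <- vapply(quals, mean, numeric(1))
    reads <- as.character(reads)
  } else {
    reads <- as.character(reads)
    meanQ <- rep(Inf, length(reads))
  }
  rejects <- c(no_primer = 0L, bad_length = 0L, ambiguous_base = 0L,
               low_quality = 0L)
  out <- character(0)
  fpLen <- nchar(forwardPrimer)
  for (i in seq_along(reads)) {
    r <- reads[i]
    fp <- regexpr(forwardPrimer, r, fixed = TRUE)
    rp <- regexpr(reversePrimer, r, fixed = TRUE)
    if (fp < 0L || rp < 0L || rp <= fp) {
      rejects["no_primer"] <- rejects["no_primer"] + 1L
      next
    }
    insert <- substr(r, fp + fpLen, rp - 1L)
    if (nchar(insert) != regionLength) {
      rejects["bad_length"] <- rejects["bad_length"] + 1L
      next
    }
    if (grepl("[^ACGT]", insert)) {
      rejects["ambiguous_base"] <- rejects["ambiguous_base"] + 1L
      next
    }
    if (meanQ[i] < minMeanQuality) {
      rejects["low_quality"] <- rejects["low_quality"] + 1L
      next
    }
    out <- c(out, insert)
  }
  attr(out, "rejects") <- rejects
  out
}

#' Write pools as TSV files with a JSON manifest
#'
#' One two-column TSV (`sequence`, `count`) per pool plus a
#' `manifest.json` recording each pool's name, round, concentration
#' (nM), polarity, total reads and expected bead coverage.
#'
#' @param poolSet a [PoolSet].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writePools <- function(poolSet, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  mat <- poolCounts(poolSet)
  info <- poolInfo(poolSet)
  manifest <- list()
  for (nm in colnames(mat)) {
    cnt <- mat[, nm]
    df <- data.frame(sequence = rownames(mat)[cnt > 0],
                     count = unname(cnt[cnt > 0]))
    df <- df[order(df$sequence), , drop = FALSE]
    file <- file.path(dir, paste0(nm, ".tsv"))
    utils::write.table(df, file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    manifest[[nm]] <- list(pool = nm, file = basename(file),
                           round = info[nm, "round"],
                           concentration = info[nm, "concentration"],
                           polarity = info[nm, "polarity"],
                           totalReads = info[nm, "totalReads"],
                           expectedCoverage = info[nm, "expectedCoverage"])
  }
  jsonlite::write_json(unname(manifest), file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read pools written by [writePools()]
#'
#' @param dir directory containing the pool TSVs and `manifest.json`.
#' @return a [PoolSet].
#' @export
readPools <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  counts <- list()
  info <- list()
  for (i in seq_len(nrow(manifest))) {
    m <- manifest[i, ]
    df <- utils::read.table(file.path(dir, m$file), header = TRUE,
                            sep = "\t", colClasses = c("character",
                                                       "integer"))
    if (sum(df$count) != m$totalReads) {
      stop("pool ", m$pool, ": TSV counts sum to ", sum(df$count),
           " but manifest says ", m$totalReads)
    }
    counts[[m$pool]] <- setNames(df$count, df$sequence)
    info[[m$pool]] <- data.frame(
      pool = m$pool, round = m$round, concentration = m$concentration,
      polarity = m$polarity, totalReads = m$totalReads,
      expectedCoverage = m$expectedCoverage)
  }
  .buildPoolSet(counts, do.call(rbind, info))
}

#' Emit a pool as FASTQ with uniform Q40 qualities
#'
#' Pipeline-compatibility output: each sequence is written once per read
#' count, flanked by the primers, with constant quality.
#'
#' @param poolSet a [PoolSet].
#' @param pool pool name (one of `colnames(poolSet)`).
#' @param path output FASTQ path.
#' @param forwardPrimer,reversePrimer primer sequences added around the
#'   variable region (defaults empty).
#' @param maxReads cap on emitted reads (default 1e5).
#' @return `path`, invisibly.
#' @export
writePoolFastq <- function(poolSet, pool, path, forwardPrimer = "",
                           reversePrimer = "", maxReads = 1e5L) {
  cnt <- poolCounts(poolSet)[, pool]
  cnt <- cnt[cnt > 0]
  reads <- rep(paste0(forwardPrimer, names(cnt), reversePrimer), cnt)
  reads <- head(reads, maxReads)
  x <- Biostrings::DNAStringSet(reads)
  names(x) <- sprintf("%s_read%06d", pool, seq_along(x))
  qual <- Biostrings::PhredQuality(
    vapply(Biostrings::width(x), function(w) strrep("I", w), character(1)))
  Biostrings::writeQualityScaledXStringSet(
    Biostrings::QualityScaledDNAStringSet(x, qual), path)
  invisible(path)
}

#' Write cluster assignments / labels / folds as TSV
#'
#' @param x a [ClusterAssignment], [StringencyLabels], or the list from
#'   [splitFolds()].
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writeTsv <- function(x, path) {
  df <- if (is(x, "ClusterAssignment")) {
    data.frame(sequence = x@sequence, cluster = x@cluster,
               phase = x@phase,
               representative = x@representative[x@cluster])
  } else if (is(x, "StringencyLabels")) {
    data.frame(sequence = rownames(x@labels), x@labels,
               check.names = FALSE)
  } else if (is.list(x) && !is.null(x$fold)) {
    data.frame(sequence = names(x$fold), fold = unname(x$fold),
               test = unname(x$fold) == x$testFold)
  } else {
    stop("unsupported object for writeTsv")
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write walk seeds as FASTA
#'
#' @param seeds character vector of seed sequences (names become FASTA
#'   ids; unnamed seeds get `seed_<i>`).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeSeedsFasta <- function(seeds, path) {
  x <- Biostrings::DNAStringSet(unname(seeds))
  ids <- names(seeds)
  if (is.null(ids) || any(ids == "")) {
    ids <- sprintf("seed_%04d", seq_along(seeds))
  }
  names(x) <- ids
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read walk seeds from FASTA
#' @param path FASTA path.
#' @return named character vector of sequences.
#' @export
readSeedsFasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' Write a walk trajectory as TSV
#' @param trajectory a [WalkTrajectory].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeTrajectory <- function(trajectory, path) {
  utils::write.table(walkTable(trajectory), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
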