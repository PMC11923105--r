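#' Hard-truncate a read pair to fixed lengths
#'
#' Forward reads are clipped to `fwdLen` (default 180 nt) and reverse reads
#' to `revLen` (default 120 nt); pairs with either mate shorter than its
#' truncation length are rejected. Truncation lengths refer to the reads
#' after barcode/binding trimming by the demultiplexer.
#'
#' @param r1,r2 Character vectors of mate sequences (equal length vectors).
#' @param fwdLen,revLen Truncation lengths in nt.
#' @return list with `r1`, `r2` (truncated, rejected pairs dropped) and
#'   `rejected` (logical over the input pairs).
#' @export
truncateReads <- function(r1, r2, fwdLen = 180L, revLen = 120L) {
  stopifnot(fwdLen > 0L, revLen > 0L, length(r1) == length(r2))
  rejected <- nchar(r1) < fwdLen | nchar(r2) < revLen
  list(r1 = substr(r1[!rejected], 1L, fwdLen),
       r2 = substr(r2[!rejected], 1L, revLen),
       rejected = rejected)
}

#' Merge truncated read pairs by overlap
#'
#' Finds the maximal-length overlap of at least `minOverlap` nt between
#' the R1 suffix and the prefix of the reverse-complemented R2, allowing
#' up to `maxMismatch` substitutions in the overlap, and returns the
#' consensus concatenation (R1 bases win at overlap mismatches, a
#' deterministic tie-break). Pairs with no qualifying overlap are
#' unmerged (`NA`). This exact overlap merge is a deliberate, documented
#' stand-in for an error-model denoiser's merge step.
#'
#' @param r1,r2 Character vectors of truncated mates.
#' @param minOverlap Minimum overlap in nt (default 12).
#' @param maxMismatch Maximum substitutions tolerated in the overlap
#'   (default 0).
#' @return Character vector of merged sequences, `NA` where unmerged.
#' @export
mergePairs <- function(r1, r2, minOverlap = 12L, maxMismatch = 0L) {
  stopifnot(length(r1) == length(r2))
  if (!length(r1)) return(character(0))
  rcr2 <- .rc(r2)
  key <- paste(r1, rcr2, sep = "\r")
  uk <- unique(key)
  merged <- vapply(uk, function(k) {
    parts <- strsplit(k, "\r", fixed = TRUE)[[1L]]
    .mergeOne(parts[1L], parts[2L], minOverlap, maxMismatch)
  }, character(1))
  unname(merged[match(key, uk)])
}

## Merge one pair; b is already reverse-complemented.
.mergeOne <- function(a, b, minOverlap, maxMismatch) {
  la <- nchar(a); lb <- nchar(b)
  top <- min(la, lb)
  if (top < minOverlap) return(NA_character_)
  ar <- charToRaw(a); br <- charToRaw(b)
  for (ov in seq.int(top, minOverlap)) {
    mm <- sum(ar[(la - ov + 1L):la] != br[seq_len(ov)])
    if (mm <= maxMismatch)
      return(paste0(a, substr(b, ov + 1L, lb)))
  }
  NA_character_
}

#' Dereplicate merged sequences into an ASV-by-well count table
#'
#' Every distinct merged sequence becomes one amplicon sequence variant;
#' counts tally its occurrences per well. Exact dereplication (no error
#' modelling) is the package's deliberate stand-in for denoising:
#' sequencing errors surface as low-count satellite ASVs that the
#' representative thresholds absorb.
#'
#' @param mergedByWell Named list: well -> character vector of merged
#'   sequences (NAs ignored). Wells with no sequences yield all-zero
#'   columns.
#' @return An [AsvCountTable-class]; ASVs are ordered by decreasing total
#'   abundance (ties by sequence) and labelled `ASV0001`, ...
#' @export
dereplicate <- function(mergedByWell) {
  wells <- names(mergedByWell)
  seqsPerWell <- lapply(mergedByWell, function(x) x[!is.na(x)])
  allSeqs <- unlist(seqsPerWell, use.names = FALSE)
  uniq <- unique(allSeqs)
  if (length(uniq)) {
    tot <- table(factor(allSeqs, levels = uniq))
    uniq <- uniq[order(-as.integer(tot), uniq)]
  }
  counts <- matrix(0L, nrow = length(uniq), ncol = length(wells),
                   dimnames = list(
                     if (length(uniq)) sprintf("ASV%04d", seq_along(uniq)),
                     wells))
  for (j in seq_along(wells)) {
    t <- table(factor(seqsPerWell[[j]], levels = uniq))
    counts[, j] <- as.integer(t)
  }
  AsvCountTable(counts, sequences = uniq)
}

#' Construct an AsvCountTable from a count matrix and ASV sequences
#'
#' @param counts Integer matrix, ASVs x wells, with dimnames.
#' @param sequences Character vector of distinct ASV sequences, one per
#'   row of `counts`.
#' @param wellInfo Optional data.frame of per-well metadata (one row per
#'   column of `counts`).
#' @return An [AsvCountTable-class].
#' @export
AsvCountTable <- function(counts, sequences, wellInfo = NULL) {
  if (is.null(rownames(counts)) && nrow(counts))
    rownames(counts) <- sprintf("ASV%04d", seq_len(nrow(counts)))
  rd <- S4Vectors::DataFrame(sequence = as.character(sequences),
                             row.names = rownames(counts))
  cd <- if (is.null(wellInfo))
    S4Vectors::DataFrame(row.names = colnames(counts))
  else S4Vectors::DataFrame(wellInfo, row.names = colnames(counts))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts), rowData = rd, colData = cd)
  new("AsvCountTable", se)
}

#' @rdname AsvCountTable
#' @param x An `AsvCountTable`.
#' @export
asvCounts <- function(x) SummarizedExperiment::assay(x, "counts")

#' @rdname AsvCountTable
#' @export
asvSequences <- function(x) {
  stats::setNames(SummarizedExperiment::rowData(x)$sequence, rownames(x))
}

#' Call representative ASVs per well
#'
#' An ASV represents a well when its count reaches `minReads` (default 15)
#' and its share of the well's total reads reaches `minProp` (default
#' 0.1). Both thresholds are inclusive ("passing" a minimum is read as
#' `>=`). Wells with zero total reads have no representatives.
#'
#' @param table An [AsvCountTable-class].
#' @param minReads Minimum read count (default 15).
#' @param minProp Minimum within-well proportion (default 0.1).
#' @return A [RepresentativeCall-class].
#' @export
callRepresentative <- function(table, minReads = 15, minProp = 0.1) {
  m <- asvCounts(table)
  totals <- colSums(m)
  prop <- sweep(m, 2L, pmax(totals, 1L), "/")
  pass <- m >= minReads & prop >= minProp & rep(totals > 0,
                                                each = nrow(m))
  hits <- which(pass, arr.ind = TRUE)
  calls <- data.frame(
    well = colnames(m)[hits[, "col"]],
    asv_id = rownames(m)[hits[, "row"]],
    count = m[hits], total = as.integer(totals[hits[, "col"]]),
    proportion = prop[hits])
  calls <- calls[order(calls$well, -calls$count, calls$asv_id), ,
                 drop = FALSE]
  rownames(calls) <- NULL
  new("RepresentativeCall", calls = calls, minReads = minReads,
      minProp = minProp, wells = colnames(m))
}

setMethod("show", "RepresentativeCall", function(object) {
  cat(sprintf(
    "RepresentativeCall: %d call(s) over %d well(s) (minReads=%g, minProp=%g)\n",
    nrow(object@calls), length(object@wells), object@minReads,
    object@minProp))
})

#' @rdname callRepresentative
#' @param calls A `RepresentativeCall`.
#' @export
representativeCalls <- function(calls) calls@calls

#' Summarize wells by representative-ASV count
#'
#' Tallies wells carrying 0, 1, 2 or 3+ representative ASVs and computes
#' the fraction of wells with at least one representative (amplification
#' success) and with exactly one (single clear genotype). Control wells
#' are tallied separately and excluded from both denominators.
#'
#' @param calls A [RepresentativeCall-class].
#' @param wellsConsidered Wells entering the summary; defaults to every
#'   well of the call object.
#' @param controls Wells treated as negative controls.
#' @return A [WellSummary-class].
#' @export
summarizeWells <- function(calls, wellsConsidered = calls@wells,
                           controls = character(0)) {
  if (!length(wellsConsidered)) stop("wellsConsidered must be nonempty")
  nRep <- vapply(wellsConsidered,
                 function(w) sum(calls@calls$well == w), integer(1))
  isCtrl <- wellsConsidered %in% controls
  perWell <- data.frame(well = wellsConsidered, n_representative = nRep,
                        is_control = isCtrl)
  cat4 <- function(x) {
    stats::setNames(as.integer(c(sum(x == 0L), sum(x == 1L), sum(x == 2L),
                                 sum(x >= 3L))), c("0", "1", "2", "3+"))
  }
  colony <- nRep[!isCtrl]
  new("WellSummary", perWell = perWell, tallies = cat4(colony),
      fractionAtLeastOne = mean(colony >= 1L),
      fractionExactlyOne = mean(colony == 1L),
      controlTallies = cat4(nRep[isCtrl]))
}

setMethod("show", "WellSummary", function(object) {
  n <- sum(!object@perWell$is_control)
  cat(sprintf("WellSummary over %d colony well(s) (+%d control(s))\n",
              n, sum(object@perWell$is_control)))
  cat(sprintf("  representatives 0/1/2/3+: %s\n",
              paste(object@tallies, collapse = "/")))
  cat(sprintf("  wells with >=1 representative: %.1f%%\n",
              100 * object@fractionAtLeastOne))
  cat(sprintf("  wells with exactly 1:          %.1f%%\n",
              100 * object@fractionExactlyOne))
})

#' Run the per-well ASV pipeline on demultiplexed reads
#'
#' Truncate, merge and dereplicate the reads of every well of a
#' [DemuxResult-class], then call representative ASVs.
#'
#' @param demux A [DemuxResult-class] (or a named list well ->
#'   list(r1, r2)).
#' @param truncFwd,truncRev Truncation lengths (defaults 180/120 nt).
#' @param minOverlap,maxOverlapMismatch Merge parameters.
#' @param minReads,minProp Representative thresholds (defaults 15 / 0.1).
#' @return list with `table` ([AsvCountTable-class]), `calls`
#'   ([RepresentativeCall-class]) and `mergeStats` (per-well input /
#'   truncated / merged read counts).
#' @export
asvPipeline <- function(demux, truncFwd = 180L, truncRev = 120L,
                        minOverlap = 12L, maxOverlapMismatch = 0L,
                        minReads = 15, minProp = 0.1) {
  reads <- if (is(demux, "DemuxResult")) demux@reads else demux
  mergedByWell <- list()
  stats <- data.frame(well = character(0), input = integer(0),
                      truncated = integer(0), merged = integer(0))
  for (key in names(reads)) {
    p <- reads[[key]]
    tr <- truncateReads(p$r1, p$r2, truncFwd, truncRev)
    mg <- mergePairs(tr$r1, tr$r2, minOverlap, maxOverlapMismatch)
    mergedByWell[[key]] <- mg[!is.na(mg)]
    stats <- rbind(stats, data.frame(
      well = key, input = length(p$r1), truncated = length(tr$r1),
      merged = sum(!is.na(mg))))
  }
  table <- dereplicate(mergedByWell)
  list(table = table, calls = callRepresentative(table, minReads, minProp),
       mergeStats = stats)
}

#' Read / write ASV count tables as TSV
#'
#' Layout: columns `asv_id`, `sequence`, then one column per well.
#'
#' @param x An [AsvCountTable-class].
#' @param file TSV path.
#' @export
writeCountTable <- function(x, file) {
  df <- data.frame(asv_id = rownames(x), sequence = asvSequences(x),
                   asvCounts(x), check.names = FALSE)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname writeCountTable
#' @export
readCountTable <- function(file) {
  df <- utils::read.table(file, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, setdiff(names(df), c("asv_id", "sequence")),
                    drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df$asv_id
  AsvCountTable(m, sequences = df$sequence)
}

#' Export ASV sequences as FASTA and representative calls as TSV
#'
#' @param x An [AsvCountTable-class].
#' @param file Output path.
#' @export
writeAsvFasta <- function(x, file) {
  seqs <- Biostrings::DNAStringSet(unname(asvSequences(x)))
  names(seqs) <- rownames(x)
  Biostrings::writeXStringSet(seqs, file)
  invisible(file)
}

#' @rdname writeAsvFasta
#' @param calls A [RepresentativeCall-class].
#' @export
writeRepresentativeCalls <- function(calls, file) {
  utils::write.table(calls@calls, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}
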