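#' Match an observed barcode against a pool with mismatch tolerance
#'
#' Returns the unique pool barcode within `maxMismatch` substitutions of
#' the observed sequence; `NO_MATCH` when none qualifies and `AMBIGUOUS`
#' when two or more pool barcodes tie at the minimal qualifying distance.
#' With pools designed at minimum pairwise distance 3 (the default from
#' [generateBarcodes()]), one mismatch can never be ambiguous.
#'
#' @param observed A single nucleotide string.
#' @param pool A [BarcodeSet-class] or named character vector of barcodes,
#'   all the same length as `observed`.
#' @param maxMismatch Maximum substitutions tolerated (default 1).
#' @return list with `status` (`MATCH`, `NO_MATCH`, `AMBIGUOUS`), `id`,
#'   `index` and `mismatches`.
#' @export
matchBarcode <- function(observed, pool, maxMismatch = 1L) {
  seqs <- if (is(pool, "BarcodeSet")) barcodeSeqs(pool) else pool
  res <- .matchBarcodesVec(observed, unname(seqs), maxMismatch)
  list(status = res$status,
       id = if (res$status == "MATCH") names(seqs)[res$idx] else NA_character_,
       index = res$idx, mismatches = res$mism)
}

## Vectorized matcher: observed (length n) vs poolSeqs (length m).
## Returns data.frame(idx, mism, status) with one row per observed string.
.matchBarcodesVec <- function(observed, poolSeqs, maxMismatch) {
  d <- .hammingMatrix(observed, poolSeqs)
  if (!nrow(d))
    return(data.frame(idx = integer(0), mism = integer(0),
                      status = character(0)))
  best <- apply(d, 1L, min)
  idx <- apply(d, 1L, which.min)
  ties <- rowSums(d == best) > 1L
  status <- ifelse(best > maxMismatch, "NO_MATCH",
                   ifelse(ties, "AMBIGUOUS", "MATCH"))
  idx[status != "MATCH"] <- NA_integer_
  data.frame(idx = idx, mism = as.integer(best), status = status)
}

#' Demultiplex paired reads to plates and wells
#'
#' Each read pair carries four indices: the exterior pair in the header
#' (`plate_ext:<FWD>+<REV>`, the sequencer's index reads) identifying the
#' plate, and the inline interior barcodes at the 5' ends of R1 and R2
#' identifying row and column. The exterior pair must match a plate of the
#' layout; when it matches no plate but both exterior barcodes are
#' individually known layout barcodes, the read is flagged `HOPPED` — the
#' signature of index hopping under a dual-unique exterior design. The
#' interior pair then resolves the well via mismatch-tolerant matching
#' (`AMBIGUOUS` on ties, `NO_MATCH` beyond tolerance or when the resolved
#' row/column is absent from the layout). Assigned reads are trimmed of
#' barcode and binding segments.
#'
#' @param r1,r2 FASTQ paths, or character vectors named by FASTQ header as
#'   returned in [SimulatedRun-class] slots.
#' @param layout A [PlateLayout-class].
#' @param cfg The [SegmentConfig-class] used for the library (determines
#'   barcode and binding-segment trim lengths).
#' @param maxMismatch Per-barcode substitution tolerance (default 1).
#' @param outDir If non-NULL, write per-well FASTQ files
#'   (`<plate>_<well>_R1.fastq` / `_R2.fastq`), the decisions TSV and a
#'   stats JSON there.
#' @return A [DemuxResult-class].
#' @export
demultiplex <- function(r1, r2, layout, cfg = segmentConfig(),
                        maxMismatch = 1L, outDir = NULL) {
  if (length(r1) == 1L && file.exists(r1[1L]) && is.null(names(r1)))
    r1 <- .readFastq(r1)
  if (length(r2) == 1L && file.exists(r2[1L]) && is.null(names(r2)))
    r2 <- .readFastq(r2)
  if (length(r1) != length(r2)) stop("R1/R2 read counts differ")
  n <- length(r1)
  headers <- names(r1)
  if (is.null(headers)) stop("reads must be named by FASTQ header")
  ids <- sub(" .*$", "", headers)

  m <- regmatches(headers,
                  regexec("plate_ext:([ACGTN]+)\\+([ACGTN]+)", headers))
  ok <- lengths(m) == 3L
  if (!all(ok)) stop("parse error: missing exterior index in header, record ",
                     which(!ok)[1L])
  extF <- vapply(m, `[`, character(1), 2L)
  extR <- vapply(m, `[`, character(1), 3L)

  bcLen <- cfg@barcodeLength
  pl <- layout@plates
  extFpool <- unique(pl$ext_fwd_seq)
  extRpool <- unique(pl$ext_rev_seq)
  mF <- .matchBarcodesVec(extF, extFpool, maxMismatch)
  mR <- .matchBarcodesVec(extR, extRpool, maxMismatch)
  pairKey <- paste(extFpool[mF$idx], extRpool[mR$idx])
  plateKey <- paste(pl$ext_fwd_seq, pl$ext_rev_seq)
  plateIdx <- match(pairKey, plateKey)
  extKnown <- mF$status == "MATCH" & mR$status == "MATCH"
  extStatus <- ifelse(!is.na(plateIdx), "PLATE",
                      ifelse(extKnown, "HOPPED", "NO_MATCH"))

  obsF <- substr(r1, 1L, bcLen)
  obsR <- substr(r2, 1L, bcLen)
  iF <- .matchBarcodesVec(obsF, layout@rowBarcodes$seq, maxMismatch)
  iR <- .matchBarcodesVec(obsR, layout@colBarcodes$seq, maxMismatch)

  status <- character(n)
  plate <- rep(NA_character_, n)
  well <- rep(NA_character_, n)
  wm <- layout@wellMap
  wellKey <- paste(wm$plate_id, wm$row, wm$col)
  candPlate <- pl$plate_id[plateIdx]
  candKey <- paste(candPlate, iF$idx, iR$idx)
  wellIdx <- match(candKey, wellKey)

  status[extStatus == "HOPPED"] <- "HOPPED"
  status[extStatus == "NO_MATCH"] <- "NO_MATCH"
  onPlate <- extStatus == "PLATE"
  intStatus <- ifelse(iF$status == "MATCH" & iR$status == "MATCH", "MATCH",
                      ifelse(iF$status == "AMBIGUOUS" |
                             iR$status == "AMBIGUOUS",
                             "AMBIGUOUS", "NO_MATCH"))
  status[onPlate & intStatus == "AMBIGUOUS"] <- "AMBIGUOUS"
  status[onPlate & intStatus == "NO_MATCH"] <- "NO_MATCH"
  assigned <- onPlate & intStatus == "MATCH" & !is.na(wellIdx)
  status[onPlate & intStatus == "MATCH" & is.na(wellIdx)] <- "NO_MATCH"
  status[assigned] <- "ASSIGNED"
  plate[assigned] <- wm$plate_id[wellIdx[assigned]]
  well[assigned] <- wm$well[wellIdx[assigned]]

  decisions <- data.frame(
    read_id = ids, status = status, plate_id = plate, well = well,
    int_fwd_mismatches = iF$mism, int_rev_mismatches = iR$mism)

  trim1 <- bcLen + nchar(cfg@bindingFwd)
  trim2 <- bcLen + nchar(cfg@bindingRev)
  reads <- list()
  if (any(assigned)) {
    key <- paste0(plate[assigned], ":", well[assigned])
    t1 <- substring(unname(r1[assigned]), trim1 + 1L)
    t2 <- substring(unname(r2[assigned]), trim2 + 1L)
    idsA <- ids[assigned]
    reads <- lapply(split(seq_along(key), key), function(j)
      list(r1 = stats::setNames(t1[j], idsA[j]),
           r2 = stats::setNames(t2[j], idsA[j])))
  }

  statusCounts <- vapply(c("ASSIGNED", "NO_MATCH", "AMBIGUOUS", "HOPPED"),
                         function(s) sum(status == s), integer(1))
  perWell <- if (any(assigned)) table(paste0(plate[assigned], ":",
                                             well[assigned])) else table(character(0))
  stats <- list(total_reads = n, status_counts = as.list(statusCounts),
                per_well = as.list(perWell))
  res <- new("DemuxResult", decisions = decisions, stats = stats,
             reads = reads)
  if (!is.null(outDir)) writeDemuxResult(res, outDir)
  res
}

setMethod("show", "DemuxResult", function(object) {
  sc <- unlist(object@stats$status_counts)
  cat(sprintf("DemuxResult: %d read pairs -> %s\n",
              object@stats$total_reads,
              paste(sprintf("%s %d", names(sc), sc), collapse = ", ")))
})

#' @rdname demultiplex
#' @param result A `DemuxResult`.
#' @export
demuxDecisions <- function(result) result@decisions

#' @rdname demultiplex
#' @export
demuxStats <- function(result) result@stats

#' @rdname demultiplex
#' @export
wellReads <- function(result) result@reads

#' Write demultiplexer outputs to a directory
#'
#' Per-well FASTQ pairs (constant Q37 qualities), `decisions.tsv` and
#' `stats.json`.
#'
#' @param result A [DemuxResult-class].
#' @param dir Output directory (created if needed).
#' @export
writeDemuxResult <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (key in names(result@reads)) {
    stem <- gsub(":", "_", key, fixed = TRUE)
    .writeFastq(result@reads[[key]]$r1,
                file.path(dir, paste0(stem, "_R1.fastq")))
    .writeFastq(result@reads[[key]]$r2,
                file.path(dir, paste0(stem, "_R2.fastq")))
  }
  utils::write.table(result@decisions, file.path(dir, "decisions.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(result@stats, file.path(dir, "stats.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}
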