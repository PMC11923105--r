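#' Construct a BarcodeSet
#'
#' @param id character, unique labels.
#' @param role character, barcode role(s); recycled to length of `id`.
#' @param sequence character, A/C/G/T sequences of one common length.
#' @return A [BarcodeSet-class] object.
#' @export
BarcodeSet <- function(id, role, sequence) {
  new("BarcodeSet", id = as.character(id),
      role = rep_len(as.character(role), length(id)),
      sequence = toupper(as.character(sequence)))
}

#' @describeIn BarcodeSet Number of barcodes in the set.
#' @param x,object A `BarcodeSet`.
#' @export
setMethod("length", "BarcodeSet", function(x) length(x@id))

#' @describeIn BarcodeSet Subset by position, id or logical mask.
#' @param i index.
#' @param j,drop,... ignored.
#' @export
setMethod("[", "BarcodeSet", function(x, i, j, ..., drop = TRUE) {
  if (is.character(i)) i <- match(i, x@id)
  BarcodeSet(x@id[i], x@role[i], x@sequence[i])
})

#' @rdname BarcodeSet
#' @export
barcodeIds <- function(x) x@id

#' @rdname BarcodeSet
#' @export
barcodeSeqs <- function(x) stats::setNames(x@sequence, x@id)

#' @rdname BarcodeSet
#' @export
barcodeRoles <- function(x) stats::setNames(x@role, x@id)

setMethod("show", "BarcodeSet", function(object) {
  cat(sprintf("BarcodeSet of %d barcode(s), width %s, role(s): %s\n",
              length(object),
              if (length(object)) nchar(object@sequence[1L]) else "-",
              paste(unique(object@role), collapse = ", ")))
  if (length(object)) {
    n <- min(length(object), 6L)
    cat(paste(sprintf("  %s\t%s\t%s", object@id[seq_len(n)],
                      object@role[seq_len(n)], object@sequence[seq_len(n)]),
              collapse = "\n"), "\n")
    if (length(object) > n) cat(sprintf("  ... and %d more\n",
                                        length(object) - n))
  }
})

#' Generate a barcode set under distance and composition constraints
#'
#' Draws random A/C/G/T sequences and greedily accepts those at pairwise
#' Hamming distance at least `minDistance` from all accepted barcodes, with
#' no homopolymer run longer than `maxHomopolymer`. The defaults (8 nt,
#' distance >= 3, homopolymer cap 3) give sets that tolerate one sequencing
#' error per barcode without ambiguity during demultiplexing.
#'
#' @param n Number of barcodes to generate.
#' @param length Barcode length in nt (default 8).
#' @param minDistance Minimum pairwise Hamming distance (default 3).
#' @param maxHomopolymer Longest allowed single-base run (default 3).
#' @param seed Integer seed; identical inputs give identical output.
#' @param role Role assigned to the generated barcodes.
#' @param prefix Id prefix; ids are `<prefix><01..n>`.
#' @return A [BarcodeSet-class] of `n` barcodes.
#' @examples
#' bc <- generateBarcodes(12, seed = 7)
#' barcodeSeqs(bc)
#' @export
generateBarcodes <- function(n, length = 8L, minDistance = 3L,
                             maxHomopolymer = 3L, seed = 1L,
                             role = "INT_FWD", prefix = "BC") {
  if (n < 1L) stop("n must be >= 1")
  if (4^length < n)
    stop("capacity error: only ", 4^length, " sequences of length ", length,
         " exist")
  if (n > 1L && minDistance > length)
    stop("capacity error: minimum distance ", minDistance,
         " is impossible at length ", length)
  set.seed(seed)
  accepted <- character(0)
  attempts <- 0L
  maxAttempts <- 5000L * n + 20000L
  while (length(accepted) < n && attempts < maxAttempts) {
    attempts <- attempts + 1L
    cand <- .randomDNA(1L, length)
    if (max(rle(strsplit(cand, "", fixed = TRUE)[[1L]])$lengths) >
        maxHomopolymer) next
    if (length(accepted) &&
        min(.hammingMatrix(cand, accepted)) < minDistance) next
    accepted <- c(accepted, cand)
  }
  if (length(accepted) < n)
    stop("capacity error: could not place ", n, " barcodes of length ",
         length, " at minimum distance ", minDistance)
  BarcodeSet(sprintf("%s%02d", prefix, seq_len(n)), role, accepted)
}

#' Generate the four barcode pools a plate layout needs
#'
#' Convenience wrapper around [generateBarcodes()] drawing one joint pool
#' and splitting it by role, so barcodes are distance-separated across roles
#' as well as within them.
#'
#' @param rows,cols,plates Plate geometry (defaults 8 x 12, 1 plate).
#' @param extExtra Additional exterior barcodes per role beyond `plates`
#'   (useful as foreign hop pools in simulations).
#' @inheritParams generateBarcodes
#' @return Named list of `BarcodeSet`s: `int_fwd`, `int_rev`, `ext_fwd`,
#'   `ext_rev`.
#' @export
generateBarcodePools <- function(rows = 8L, cols = 12L, plates = 1L,
                                 extExtra = 0L, length = 8L,
                                 minDistance = 3L, maxHomopolymer = 3L,
                                 seed = 1L) {
  nExt <- plates + extExtra
  total <- rows + cols + 2L * nExt
  all <- generateBarcodes(total, length = length, minDistance = minDistance,
                          maxHomopolymer = maxHomopolymer, seed = seed,
                          prefix = "BC")
  sq <- barcodeSeqs(all)
  idx <- 0L
  take <- function(k, role, prefix) {
    out <- BarcodeSet(sprintf("%s%02d", prefix, seq_len(k)), role,
                      unname(sq[idx + seq_len(k)]))
    idx <<- idx + k
    out
  }
  list(int_fwd = take(rows, "INT_FWD", "IF"),
       int_rev = take(cols, "INT_REV", "IR"),
       ext_fwd = take(nExt, "EXT_FWD", "EF"),
       ext_rev = take(nExt, "EXT_REV", "ER"))
}

#' Default primer segment configuration
#'
#' Ships Illumina Nextera-style P5/P7 adapters and overlap regions with
#' 515F/806R-style 16S V4 binding segments. The adapter and overlap strings
#' are conventional defaults, not a vendor reference; override any segment
#' for other loci or chemistries.
#'
#' @param p5Adapter,p7Adapter Flow-cell adapters (strict A/C/G/T).
#' @param nexteraFwd,nexteraRev Overlap regions through which the exterior
#'   primers prime on the interior product.
#' @param bindingFwd,bindingRev Locus-binding segments; IUPAC degeneracy
#'   allowed (the 515F/806R defaults are degenerate).
#' @param barcodeLength Barcode length in nt (default 8).
#' @return A [SegmentConfig-class] object.
#' @export
segmentConfig <- function(p5Adapter = "AATGATACGGCGACCACCGAGATCTACAC",
                          p7Adapter = "CAAGCAGAAGACGGCATACGAGAT",
                          nexteraFwd = "TCGTCGGCAGCGTCAGATGTGTATAAGAGACAG",
                          nexteraRev = "GTCTCGTGGGCTCGGAGATGTGTATAAGAGACAG",
                          bindingFwd = "GTGYCAGCMGCCGCGGTAA",
                          bindingRev = "GGACTACNVGGGTWTCTAAT",
                          barcodeLength = 8L) {
  new("SegmentConfig", p5Adapter = toupper(p5Adapter),
      p7Adapter = toupper(p7Adapter), nexteraFwd = toupper(nexteraFwd),
      nexteraRev = toupper(nexteraRev), bindingFwd = toupper(bindingFwd),
      bindingRev = toupper(bindingRev),
      barcodeLength = as.integer(barcodeLength))
}

setMethod("show", "SegmentConfig", function(object) {
  cat("SegmentConfig\n",
      sprintf("  p5 adapter   %s\n", object@p5Adapter),
      sprintf("  p7 adapter   %s\n", object@p7Adapter),
      sprintf("  nextera fwd  %s\n", object@nexteraFwd),
      sprintf("  nextera rev  %s\n", object@nexteraRev),
      sprintf("  binding fwd  %s\n", object@bindingFwd),
      sprintf("  binding rev  %s\n", object@bindingRev),
      sprintf("  barcode      %d nt\n", object@barcodeLength), sep = "")
})

#' Assemble one primer from a barcode and the segment configuration
#'
#' Interior primers are (overlap, barcode, binding); exterior primers are
#' (flow-cell adapter, barcode, overlap). The barcode's role must match the
#' requested primer role.
#'
#' @param role One of `INT_FWD`, `INT_REV`, `EXT_FWD`, `EXT_REV`.
#' @param barcode A length-1 [BarcodeSet-class] (or a larger set plus `i`).
#' @param cfg A [SegmentConfig-class].
#' @param i Index into `barcode` when it holds several barcodes.
#' @return A [Primer-class] object.
#' @export
assemblePrimer <- function(role, barcode, cfg = segmentConfig(), i = 1L) {
  role <- match.arg(role, BC_ROLES)
  bcRole <- barcode@role[i]
  if (!identical(bcRole, role))
    stop("role error: barcode has role ", bcRole, ", primer requires ", role)
  bcSeq <- barcode@sequence[i]
  if (nchar(bcSeq) != cfg@barcodeLength)
    stop("barcode length ", nchar(bcSeq), " does not match configured ",
         cfg@barcodeLength)
  segments <- switch(role,
    INT_FWD = c(nextera_fwd = cfg@nexteraFwd, barcode = bcSeq,
                binding_fwd = cfg@bindingFwd),
    INT_REV = c(nextera_rev = cfg@nexteraRev, barcode = bcSeq,
                binding_rev = cfg@bindingRev),
    EXT_FWD = c(p5_adapter = cfg@p5Adapter, barcode = bcSeq,
                nextera_fwd = cfg@nexteraFwd),
    EXT_REV = c(p7_adapter = cfg@p7Adapter, barcode = bcSeq,
                nextera_rev = cfg@nexteraRev))
  new("Primer", role = role, barcodeId = barcode@id[i], barcode = bcSeq,
      segments = segments, fullSequence = paste(segments, collapse = ""))
}

setMethod("show", "Primer", function(object) {
  cat(sprintf("Primer %s [%s]\n  %s\n  segments: %s\n",
              object@role, object@barcodeId, object@fullSequence,
              paste(sprintf("%s(%d)", names(object@segments),
                            nchar(object@segments)), collapse = " + ")))
})

#' Read / write barcode tables
#'
#' Barcode tables are TSV with columns `id`, `role`, `sequence`.
#'
#' @param file Path to a TSV file.
#' @return `importBarcodes` returns a [BarcodeSet-class].
#' @export
importBarcodes <- function(file) {
  tb <- utils::read.table(file, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  BarcodeSet(tb$id, tb$role, tb$sequence)
}

#' @rdname importBarcodes
#' @param x A `BarcodeSet`.
#' @export
exportBarcodes <- function(x, file) {
  utils::write.table(
    data.frame(id = x@id, role = x@role, sequence = x@sequence),
    file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Export assembled primers as FASTA
#'
#' One record per primer, id `<role>_<barcode id>`. Degenerate binding
#' bases are kept as IUPAC codes.
#'
#' @param primers A list of [Primer-class] objects.
#' @param file Output FASTA path.
#' @export
exportPrimersFasta <- function(primers, file) {
  seqs <- Biostrings::DNAStringSet(
    vapply(primers, function(p) p@fullSequence, character(1)))
  names(seqs) <- vapply(primers,
                        function(p) paste0(p@role, "_", p@barcodeId),
                        character(1))
  Biostrings::writeXStringSet(seqs, file)
  invisible(file)
}
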