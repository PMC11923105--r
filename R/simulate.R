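#' Generate synthetic 16S-V4-like template inserts
#'
#' Draws a random ancestor of `insertLength` nt and derives each taxon by
#' substituting each position independently with probability
#' `divergence / 2`, so any two taxa differ at approximately `divergence`
#' of their positions. Synthetic templates exercise the pipeline's
#' geometry and barcoding; they do not model real 16S composition,
#' conserved blocks or secondary structure.
#'
#' @param nTaxa Number of template sequences.
#' @param insertLength Insert length in nt (default 254, the 16S V4 target).
#' @param divergence Expected pairwise substitution fraction in `[0, 1]`.
#' @param seed Integer seed.
#' @return A named [Biostrings::DNAStringSet] (`taxon_01`, ...).
#' @export
generateTemplates <- function(nTaxa, insertLength = 254L, divergence = 0.05,
                              seed = 1L) {
  if (nTaxa < 1L) stop("nTaxa must be >= 1")
  if (divergence < 0 || divergence > 1) stop("divergence must be in [0, 1]")
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  anc <- sample(bases, insertLength, replace = TRUE)
  seqs <- vapply(seq_len(nTaxa), function(i) {
    s <- anc
    hit <- which(stats::runif(insertLength) < divergence / 2)
    if (length(hit))
      s[hit] <- vapply(s[hit], function(b) sample(setdiff(bases, b), 1L),
                       character(1))
    paste(s, collapse = "")
  }, character(1))
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- sprintf("taxon_%02d", seq_len(nTaxa))
  out
}

#' Assign templates (and empty controls) to wells
#'
#' @param layout A [PlateLayout-class].
#' @param templateIds Character vector of template names to draw from.
#' @param nControls Number of wells left empty as negative controls
#'   (default 3); chosen at random among the layout's wells.
#' @param seed Integer seed.
#' @return data.frame: plate_id, well, template_id (`"EMPTY"` for
#'   controls), is_control.
#' @export
makeAssignment <- function(layout, templateIds, nControls = 3L, seed = 1L) {
  wm <- layout@wellMap
  set.seed(seed)
  n <- nrow(wm)
  if (nControls > n) stop("more controls than wells")
  ctrl <- sample.int(n, nControls)
  tid <- sample(templateIds, n, replace = TRUE)
  tid[ctrl] <- "EMPTY"
  data.frame(plate_id = wm$plate_id, well = wm$well, template_id = tid,
             is_control = seq_len(n) %in% ctrl)
}

#' Build the four-primer amplicon for one well
#'
#' Assembles the top strand of the final product: P5, exterior-forward
#' barcode, forward overlap, interior-forward barcode, forward binding
#' segment, insert, then the reverse-complemented reverse-side segments
#' (binding, interior-reverse barcode, overlap, exterior-reverse barcode,
#' P7). Degenerate IUPAC bases in the binding segments are resolved to the
#' lexicographically smallest compatible base, since a physical molecule
#' has concrete bases.
#'
#' @param template A single template sequence (character or
#'   `DNAStringSet` element); its name is recorded as the template id.
#' @param well Well name (e.g. `"A01"`).
#' @param layout A [PlateLayout-class].
#' @param cfg A [SegmentConfig-class].
#' @param plateId Plate id; default the layout's first plate.
#' @return An [Amplicon-class].
#' @export
buildAmplicon <- function(template, well, layout, cfg = segmentConfig(),
                          plateId = layout@plates$plate_id[1L]) {
  wm <- layout@wellMap
  hit <- which(wm$plate_id == plateId & wm$well == well)
  if (length(hit) != 1L)
    stop("lookup error: well ", well, " not found on plate ", plateId)
  w <- wm[hit, ]
  tid <- if (!is.null(names(template)) && nzchar(names(template)[1L]))
    names(template)[1L] else "template"
  insert <- unname(toupper(as.character(template)[1L]))
  segments <- c(
    p5 = cfg@p5Adapter,
    ext_fwd_bc = w$ext_fwd_seq,
    nextera_fwd = cfg@nexteraFwd,
    int_fwd_bc = w$int_fwd_seq,
    binding_fwd = .disambiguate(cfg@bindingFwd),
    insert = insert,
    binding_rev_rc = .rc(.disambiguate(cfg@bindingRev)),
    int_rev_bc_rc = .rc(w$int_rev_seq),
    nextera_rev_rc = .rc(cfg@nexteraRev),
    ext_rev_bc_rc = .rc(w$ext_rev_seq),
    p7_rc = .rc(cfg@p7Adapter))
  new("Amplicon", segments = segments, plateId = plateId, well = well,
      templateId = tid)
}

#' @rdname buildAmplicon
#' @param amplicon An `Amplicon`.
#' @export
ampliconSequence <- function(amplicon) {
  paste(amplicon@segments, collapse = "")
}

#' @rdname buildAmplicon
#' @export
ampliconBarcodes <- function(amplicon) {
  s <- amplicon@segments
  c(int_fwd = unname(s["int_fwd_bc"]),
    int_rev = .rc(unname(s["int_rev_bc_rc"])),
    ext_fwd = unname(s["ext_fwd_bc"]),
    ext_rev = .rc(unname(s["ext_rev_bc_rc"])))
}

setMethod("show", "Amplicon", function(object) {
  cat(sprintf("Amplicon %s %s (template %s), %d nt\n  %s\n",
              object@plateId, object@well, object@templateId,
              sum(nchar(object@segments)),
              paste(sprintf("%s(%d)", names(object@segments),
                            nchar(object@segments)), collapse = " + ")))
})

#' Simulate a paired-end sequencing run of a barcoded plate set
#'
#' Builds the amplicon for every non-empty well, then emits
#' `readsPerWell` read pairs per well. R1 starts at the interior-forward
#' barcode on the top strand; R2 starts at the interior-reverse barcode on
#' the bottom strand (the sequencing primers anneal in the overlap
#' regions). The exterior index pair observed by the sequencer travels in
#' the read header as `plate_ext:<FWD>+<REV>`, modelling
#' sequencer-side index reads. Uniform per-base substitution errors are
#' applied to both mates at `subErrorRate`. With probability `hopRate` a
#' read undergoes index hopping: a fair coin picks the exterior forward or
#' reverse index, which is replaced by a different barcode drawn from
#' `hopPool` — modelling a free adaptor swapped in during clustering.
#'
#' @param layout A [PlateLayout-class].
#' @param assignment data.frame from [makeAssignment()] (columns plate_id,
#'   well, template_id; `"EMPTY"` wells yield no reads).
#' @param templates Named `DNAStringSet` of inserts.
#' @param readsPerWell Read pairs per non-empty well (default 200).
#' @param readLength Read length in nt (default 300, 300x2 chemistry).
#' @param subErrorRate Per-base substitution probability (default 0).
#' @param hopRate Per-read index-hopping probability (default 0).
#' @param seed Integer seed; identical inputs give identical output.
#' @param cfg A [SegmentConfig-class].
#' @param hopPool Named list with `ext_fwd` and `ext_rev` character vectors
#'   of candidate replacement barcodes. Default: the layout's own exterior
#'   barcodes (requires >= 2 plates when `hopRate > 0`; pass foreign
#'   barcodes to hop a single-plate run).
#' @param outPrefix If non-NULL, write `<prefix>_R1.fastq`,
#'   `<prefix>_R2.fastq` and `<prefix>_truth.tsv`.
#' @return A [SimulatedRun-class].
#' @export
simulateRun <- function(layout, assignment, templates, readsPerWell = 200L,
                        readLength = 300L, subErrorRate = 0, hopRate = 0,
                        seed = 1L, cfg = segmentConfig(), hopPool = NULL,
                        outPrefix = NULL) {
  stopifnot(subErrorRate >= 0, subErrorRate <= 1, hopRate >= 0, hopRate <= 1,
            readsPerWell >= 0)
  filled <- assignment[assignment$template_id != "EMPTY", , drop = FALSE]
  if (nrow(filled) && !all(filled$template_id %in% names(templates)))
    stop("config error: assignment references unknown template ids")
  if (is.null(hopPool))
    hopPool <- list(ext_fwd = unique(layout@plates$ext_fwd_seq),
                    ext_rev = unique(layout@plates$ext_rev_seq))
  if (hopRate > 0 &&
      (length(hopPool$ext_fwd) < 2L || length(hopPool$ext_rev) < 2L))
    stop("config error: hopRate > 0 needs >= 2 candidate exterior barcodes",
         " per side (multi-plate layout or explicit hopPool)")
  set.seed(seed)

  bcLen <- cfg@barcodeLength
  r1Start <- nchar(cfg@p5Adapter) + bcLen + nchar(cfg@nexteraFwd) + 1L
  r2Start <- nchar(cfg@p7Adapter) + bcLen + nchar(cfg@nexteraRev) + 1L

  r1 <- r2 <- extF <- extR <- character(0)
  plate <- well <- tmpl <- character(0)
  for (i in seq_len(nrow(filled))) {
    a <- filled[i, ]
    amp <- buildAmplicon(templates[a$template_id], a$well, layout,
                         cfg = cfg, plateId = a$plate_id)
    top <- ampliconSequence(amp)
    bottom <- .rc(top)
    one1 <- substr(top, r1Start, min(nchar(top), r1Start + readLength - 1L))
    one2 <- substr(bottom, r2Start,
                   min(nchar(bottom), r2Start + readLength - 1L))
    bcs <- ampliconBarcodes(amp)
    r1 <- c(r1, rep(one1, readsPerWell))
    r2 <- c(r2, rep(one2, readsPerWell))
    extF <- c(extF, rep(unname(bcs["ext_fwd"]), readsPerWell))
    extR <- c(extR, rep(unname(bcs["ext_rev"]), readsPerWell))
    plate <- c(plate, rep(a$plate_id, readsPerWell))
    well <- c(well, rep(a$well, readsPerWell))
    tmpl <- c(tmpl, rep(a$template_id, readsPerWell))
  }
  n <- length(r1)

  hopped <- if (n) stats::runif(n) < hopRate else logical(0)
  if (any(hopped)) {
    side <- stats::runif(n) < 0.5  # TRUE: swap forward index
    for (i in which(hopped)) {
      if (side[i]) {
        cand <- setdiff(hopPool$ext_fwd, extF[i])
        extF[i] <- cand[sample.int(length(cand), 1L)]
      } else {
        cand <- setdiff(hopPool$ext_rev, extR[i])
        extR[i] <- cand[sample.int(length(cand), 1L)]
      }
    }
  }

  r1 <- .addSubstitutions(r1, subErrorRate)
  r2 <- .addSubstitutions(r2, subErrorRate)

  ids <- sprintf("read%06d", seq_len(n))
  headers <- sprintf("%s plate_ext:%s+%s", ids, extF, extR)
  names(r1) <- headers
  names(r2) <- headers
  truth <- data.frame(read_id = ids, plate_id = plate, well = well,
                      template_id = tmpl, hopped = as.integer(hopped))
  run <- new("SimulatedRun", r1 = r1, r2 = r2, truth = truth)
  if (!is.null(outPrefix)) writeSimulatedRun(run, outPrefix)
  run
}

setMethod("show", "SimulatedRun", function(object) {
  cat(sprintf("SimulatedRun: %d read pairs, %d wells, %d hopped\n",
              length(object@r1), length(unique(object@truth$well)),
              sum(object@truth$hopped)))
})

#' Write a simulated run as FASTQ pairs plus ground truth
#'
#' Emits `<prefix>_R1.fastq`, `<prefix>_R2.fastq` (constant Q37 quality)
#' and `<prefix>_truth.tsv`.
#'
#' @param run A [SimulatedRun-class].
#' @param prefix Output path prefix.
#' @return The three file paths, invisibly.
#' @export
writeSimulatedRun <- function(run, prefix) {
  f1 <- paste0(prefix, "_R1.fastq")
  f2 <- paste0(prefix, "_R2.fastq")
  ft <- paste0(prefix, "_truth.tsv")
  .writeFastq(run@r1, f1)
  .writeFastq(run@r2, f2)
  utils::write.table(run@truth, ft, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(r1 = f1, r2 = f2, truth = ft))
}

## Constant-quality FASTQ writer; x is a character vector named by header.
.writeFastq <- function(x, file) {
  qual <- vapply(nchar(x), function(w) strrep("F", w), character(1))
  writeLines(as.vector(rbind(paste0("@", names(x)), unname(x), "+", qual)),
             file)
  invisible(file)
}

## FASTQ reader returning sequences named by the full header line.
.readFastq <- function(file) {
  x <- Biostrings::readDNAStringSet(file, format = "fastq")
  stats::setNames(as.character(x), names(x))
}
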