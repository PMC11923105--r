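#' @import methods
#' @importFrom S4Vectors DataFrame
NULL

## Barcode roles used throughout: interior primers carry inline sample
## barcodes read as part of R1/R2; exterior primers carry the i5/i7-style
## plate indices read by the sequencer.
BC_ROLES <- c("INT_FWD", "INT_REV", "EXT_FWD", "EXT_REV")

.IUPAC_ONLY <- c("R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "N")

#' BarcodeSet: a set of index sequences sharing a role
#'
#' Holds short index ("barcode") sequences together with their role in the
#' four-primer amplicon. Barcodes are strict A/C/G/T (no IUPAC degeneracy) so
#' that demultiplexing is unambiguous, all have equal length (8 nt in the
#' shipped design), and ids are unique.
#'
#' @slot id character, unique short labels.
#' @slot role character, one of `INT_FWD`, `INT_REV`, `EXT_FWD`, `EXT_REV`
#'   (one value per barcode; a set usually has a single role).
#' @slot sequence character, the barcode sequences.
#' @export
setClass("BarcodeSet",
  slots = c(id = "character", role = "character", sequence = "character"))

setValidity("BarcodeSet", function(object) {
  n <- length(object@id)
  if (length(object@role) != n || length(object@sequence) != n)
    return("id, role and sequence must have equal length")
  if (n == 0L) return(TRUE)
  if (anyDuplicated(object@id)) return("barcode ids must be unique")
  if (!all(object@role %in% BC_ROLES))
    return(sprintf("role must be one of %s", paste(BC_ROLES, collapse = ", ")))
  if (length(unique(nchar(object@sequence))) != 1L)
    return("all barcode sequences must have the same length")
  if (any(grepl("[^ACGT]", object@sequence)))
    return("barcode sequences must contain only A/C/G/T")
  TRUE
})

#' SegmentConfig: fixed technical segments of the four primer species
#'
#' The non-barcode building blocks of the primers: flow-cell adapters (P5/P7)
#' on the exterior primers, the Nextera-style overlap regions through which
#' exterior primers prime on the interior product, and the locus-binding
#' segments (515F/806R-style for 16S V4). IUPAC degeneracy is permitted only
#' in the binding segments; everything else is strict A/C/G/T.
#'
#' The shipped adapter/overlap defaults follow the standard Illumina
#' Nextera-style sequences but are configuration, not a reference standard;
#' swap in your own with [segmentConfig()].
#'
#' @slot p5Adapter,p7Adapter character(1), flow-cell adapters.
#' @slot nexteraFwd,nexteraRev character(1), overlap regions shared between
#'   interior and exterior primers.
#' @slot bindingFwd,bindingRev character(1), locus-binding segments
#'   (degenerate bases allowed).
#' @slot barcodeLength integer(1), barcode length in nt (default 8).
#' @export
setClass("SegmentConfig",
  slots = c(p5Adapter = "character", p7Adapter = "character",
            nexteraFwd = "character", nexteraRev = "character",
            bindingFwd = "character", bindingRev = "character",
            barcodeLength = "integer"))

setValidity("SegmentConfig", function(object) {
  strict <- c(p5Adapter = object@p5Adapter, p7Adapter = object@p7Adapter,
              nexteraFwd = object@nexteraFwd, nexteraRev = object@nexteraRev)
  bind <- c(bindingFwd = object@bindingFwd, bindingRev = object@bindingRev)
  if (any(!nzchar(c(strict, bind)))) return("all segments must be non-empty")
  if (any(grepl("[^ACGT]", strict)))
    return("adapter and overlap segments must be strict A/C/G/T")
  if (any(grepl(sprintf("[^ACGT%s]", paste(.IUPAC_ONLY, collapse = "")), bind)))
    return("binding segments must be IUPAC nucleotide codes")
  if (length(object@barcodeLength) != 1L || object@barcodeLength < 1L)
    return("barcodeLength must be a single positive integer")
  TRUE
})

#' Primer: one assembled primer species
#'
#' An ordered list of named segments and the full sequence they concatenate
#' to. Interior primers are (overlap, barcode, binding); exterior primers are
#' (adapter, barcode, overlap).
#'
#' @slot role character(1), the primer role.
#' @slot barcodeId character(1), id of the embedded barcode.
#' @slot barcode character(1), the barcode sequence.
#' @slot segments named character, segments in 5'-to-3' order.
#' @slot fullSequence character(1), concatenation of the segments.
#' @export
setClass("Primer",
  slots = c(role = "character", barcodeId = "character", barcode = "character",
            segments = "character", fullSequence = "character"))

setValidity("Primer", function(object) {
  if (!object@role %in% BC_ROLES) return("invalid role")
  if (!identical(object@fullSequence,
                 paste(object@segments, collapse = "")))
    return("fullSequence must equal the concatenation of segments")
  if (!object@barcode %in% object@segments)
    return("barcode must appear among the segments")
  TRUE
})

#' PlateLayout: well-to-barcode mapping for one or more plates
#'
#' Implements the four-barcode row/column/plate encoding: every well of a
#' plate is identified by its row's interior-forward barcode and its column's
#' interior-reverse barcode, and every plate by one exterior
#' forward/reverse pair. Under the default `"dual_unique"` exterior design no
#' exterior barcode is reused across plates, so a single hopped exterior
#' index always produces a pair that exists on no plate (detectable). The
#' `"combinatorial"` design reuses exterior barcodes across a plate grid and
#' is provided to demonstrate silent misassignment under index hopping.
#'
#' @slot plates data.frame with columns plate_id, ext_fwd_id, ext_fwd_seq,
#'   ext_rev_id, ext_rev_seq.
#' @slot rowBarcodes,colBarcodes data.frame with columns id, seq; the
#'   interior-forward (row) and interior-reverse (column) barcodes shared by
#'   all plates.
#' @slot wellMap data.frame, one row per well: plate_id, well, row, col and
#'   the four barcode ids + sequences.
#' @slot extDesign character(1), `"dual_unique"` or `"combinatorial"`.
#' @export
setClass("PlateLayout",
  slots = c(plates = "data.frame", rowBarcodes = "data.frame",
            colBarcodes = "data.frame", wellMap = "data.frame",
            extDesign = "character"))

setValidity("PlateLayout", function(object) {
  wm <- object@wellMap
  need <- c("plate_id", "well", "row", "col",
            "int_fwd_id", "int_fwd_seq", "int_rev_id", "int_rev_seq",
            "ext_fwd_id", "ext_fwd_seq", "ext_rev_id", "ext_rev_seq")
  if (!all(need %in% names(wm)))
    return(sprintf("wellMap lacks columns: %s",
                   paste(setdiff(need, names(wm)), collapse = ", ")))
  if (!object@extDesign %in% c("dual_unique", "combinatorial"))
    return("extDesign must be 'dual_unique' or 'combinatorial'")
  ## every well maps to exactly four barcodes, interior pairs unique per plate
  if (any(is.na(wm[, need]))) return("wellMap must not contain NA")
  pairkey <- paste(wm$plate_id, wm$int_fwd_id, wm$int_rev_id)
  if (anyDuplicated(pairkey))
    return("interior (fwd, rev) barcode pairs must be unique within a plate")
  pl <- object@plates
  if (anyDuplicated(paste(pl$ext_fwd_id, pl$ext_rev_id)))
    return("exterior barcode pairs must be unique across plates")
  if (object@extDesign == "dual_unique" &&
      (anyDuplicated(pl$ext_fwd_id) || anyDuplicated(pl$ext_rev_id)))
    return("dual-unique design: exterior barcodes must not be reused across plates")
  TRUE
})

#' Amplicon: the segment model of one four-primer product
#'
#' The final amplicon, top strand 5'-to-3'. Segments originating from the
#' reverse primers are stored reverse-complemented so that the full sequence
#' is the plain concatenation of the segments.
#'
#' @slot segments named character, in order: p5, ext_fwd_bc, nextera_fwd,
#'   int_fwd_bc, binding_fwd, insert, binding_rev_rc, int_rev_bc_rc,
#'   nextera_rev_rc, ext_rev_bc_rc, p7_rc.
#' @slot plateId,well character(1), the well of origin.
#' @slot templateId character(1), id of the template the insert came from.
#' @export
setClass("Amplicon",
  slots = c(segments = "character", plateId = "character",
            well = "character", templateId = "character"))

AMPLICON_SEGMENTS <- c("p5", "ext_fwd_bc", "nextera_fwd", "int_fwd_bc",
                       "binding_fwd", "insert", "binding_rev_rc",
                       "int_rev_bc_rc", "nextera_rev_rc", "ext_rev_bc_rc",
                       "p7_rc")

setValidity("Amplicon", function(object) {
  if (!identical(names(object@segments), AMPLICON_SEGMENTS))
    return("segments must be named and ordered as the amplicon structure")
  if (any(grepl("[^ACGT]", object@segments)))
    return("amplicon segments must be concrete A/C/G/T sequences")
  TRUE
})

#' SimulatedRun: paired reads plus ground truth from the simulator
#'
#' @slot r1,r2 character, read sequences named by their FASTQ headers
#'   (`"<id> plate_ext:<FWD>+<REV>"`); the exterior index pair observed by
#'   the sequencer travels in the header.
#' @slot truth data.frame: read_id, plate_id, well, template_id, hopped.
#' @export
setClass("SimulatedRun",
  slots = c(r1 = "character", r2 = "character", truth = "data.frame"))

setValidity("SimulatedRun", function(object) {
  if (length(object@r1) != length(object@r2))
    return("r1 and r2 must have equal length")
  if (nrow(object@truth) != length(object@r1))
    return("truth must have one row per read pair")
  TRUE
})

#' DemuxResult: per-read assignment decisions, statistics and trimmed reads
#'
#' @slot decisions data.frame: read_id, status (ASSIGNED / NO_MATCH /
#'   AMBIGUOUS / HOPPED), plate_id, well, int_fwd_mismatches,
#'   int_rev_mismatches.
#' @slot stats list: total_reads, per-status counts, per-well read counts.
#' @slot reads named list, one element per well (`"<plate>:<well>"`) holding
#'   list(r1, r2) of barcode- and binding-trimmed read sequences.
#' @export
setClass("DemuxResult",
  slots = c(decisions = "data.frame", stats = "list", reads = "list"))

setValidity("DemuxResult", function(object) {
  st <- object@stats
  cnt <- sum(unlist(st$status_counts))
  if (length(cnt) && !identical(as.integer(cnt), as.integer(st$total_reads)))
    return("per-status counts must sum to total_reads")
  TRUE
})

#' AsvCountTable: ASV-by-well read counts
#'
#' Extends [SummarizedExperiment::SummarizedExperiment] with a `counts`
#' assay; rows are distinct amplicon sequence variants (exact merged
#' sequences), columns are wells. Row metadata carries the ASV sequence.
#'
#' @export
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
setClass("AsvCountTable", contains = "SummarizedExperiment")

setValidity("AsvCountTable", function(object) {
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    return("must contain a 'counts' assay")
  m <- SummarizedExperiment::assay(object, "counts")
  if (any(m < 0)) return("counts must be non-negative")
  sq <- SummarizedExperiment::rowData(object)$sequence
  if (is.null(sq)) return("rowData must carry a 'sequence' column")
  if (anyDuplicated(sq)) return("ASV sequences must be distinct")
  TRUE
})

#' RepresentativeCall: representative ASVs per well
#'
#' ASVs passing both the absolute read threshold (default 15 reads) and the
#' within-well proportion threshold (default 0.1 of the well's total reads).
#'
#' @slot calls data.frame: well, asv_id, count, total, proportion.
#' @slot minReads,minProp numeric(1), the thresholds used.
#' @slot wells character, every well the call considered (including wells
#'   with no representative).
#' @export
setClass("RepresentativeCall",
  slots = c(calls = "data.frame", minReads = "numeric", minProp = "numeric",
            wells = "character"))

setValidity("RepresentativeCall", function(object) {
  cl <- object@calls
  if (nrow(cl)) {
    if (any(cl$count < object@minReads))
      return("all calls must meet the read threshold")
    if (any(cl$proportion < object@minProp))
      return("all calls must meet the proportion threshold")
    if (!all(cl$well %in% object@wells))
      return("called wells must be among the considered wells")
  }
  TRUE
})

#' WellSummary: per-well representative tallies and success fractions
#'
#' @slot perWell data.frame: well, n_representative, is_control.
#' @slot tallies named integer, wells with 0, 1, 2 and 3+ representatives
#'   (controls excluded).
#' @slot fractionAtLeastOne,fractionExactlyOne numeric(1), fractions over
#'   the non-control wells considered.
#' @slot controlTallies named integer, same categories for control wells.
#' @export
setClass("WellSummary",
  slots = c(perWell = "data.frame", tallies = "integer",
            fractionAtLeastOne = "numeric", fractionExactlyOne = "numeric",
            controlTallies = "integer"))

setValidity("WellSummary", function(object) {
  n <- sum(!object@perWell$is_control)
  if (sum(object@tallies) != n)
    return("category tallies must sum to the number of non-control wells")
  TRUE
})

#' WorkflowCostModel: cost components of one genotyping workflow
#'
#' Components accrue per sample, per plate (amortized over the plate's
#' wells) or per pool (amortized over all colonies in the run).
#'
#' @slot name character(1), workflow name.
#' @slot components data.frame: component, basis (per_sample / per_plate /
#'   per_pool), unit_cost.
#' @slot wellsPerPlate integer(1).
#' @export
setClass("WorkflowCostModel",
  slots = c(name = "character", components = "data.frame",
            wellsPerPlate = "integer"))

setValidity("WorkflowCostModel", function(object) {
  cmp <- object@components
  if (!all(c("component", "basis", "unit_cost") %in% names(cmp)))
    return("components needs columns component, basis, unit_cost")
  if (!all(cmp$basis %in% c("per_sample", "per_plate", "per_pool")))
    return("basis must be per_sample, per_plate or per_pool")
  if (any(cmp$unit_cost < 0)) return("unit costs must be non-negative")
  if (object@wellsPerPlate < 1L) return("wellsPerPlate must be positive")
  TRUE
})
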