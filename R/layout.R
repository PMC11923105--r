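#' Build a multi-plate four-barcode layout
#'
#' Rows share an interior-forward barcode, columns an interior-reverse
#' barcode, and each plate is labelled by one exterior forward/reverse pair.
#' Under the default dual-unique exterior design plate k consumes the k-th
#' barcode of both exterior pools, so no exterior barcode recurs and a
#' single hopped exterior index always yields a pair absent from the
#' layout. The `"combinatorial"` design instead arranges plates on a grid
#' and reuses exterior barcodes along its rows and columns; it needs fewer
#' exterior barcodes but a hopped index can land on another plate's valid
#' pair undetected.
#'
#' @param nPlates,rows,cols Geometry (defaults 1 plate of 8 x 12).
#' @param pools Named list with `int_fwd`, `int_rev`, `ext_fwd`, `ext_rev`
#'   [BarcodeSet-class] pools, e.g. from [generateBarcodePools()].
#' @param extDesign `"dual_unique"` (default) or `"combinatorial"`.
#' @return A [PlateLayout-class].
#' @examples
#' pools <- generateBarcodePools(seed = 1)
#' layout <- buildLayout(1, 8, 12, pools)
#' layout
#' @export
buildLayout <- function(nPlates = 1L, rows = 8L, cols = 12L, pools,
                        extDesign = c("dual_unique", "combinatorial")) {
  extDesign <- match.arg(extDesign)
  if (rows > 26L) stop("at most 26 rows supported (letter naming)")
  nExtF <- if (extDesign == "dual_unique") nPlates
           else ceiling(sqrt(nPlates))
  nExtR <- if (extDesign == "dual_unique") nPlates
           else ceiling(nPlates / ceiling(sqrt(nPlates)))
  if (length(pools$int_fwd) < rows)
    stop("capacity error: need ", rows, " INT_FWD barcodes, pool has ",
         length(pools$int_fwd))
  if (length(pools$int_rev) < cols)
    stop("capacity error: need ", cols, " INT_REV barcodes, pool has ",
         length(pools$int_rev))
  if (length(pools$ext_fwd) < nExtF || length(pools$ext_rev) < nExtR)
    stop("capacity error: exterior pools too small for ", nPlates, " plates")

  rowBc <- data.frame(id = pools$int_fwd@id[seq_len(rows)],
                      seq = pools$int_fwd@sequence[seq_len(rows)])
  colBc <- data.frame(id = pools$int_rev@id[seq_len(cols)],
                      seq = pools$int_rev@sequence[seq_len(cols)])
  k <- seq_len(nPlates)
  if (extDesign == "dual_unique") {
    fIdx <- k; rIdx <- k
  } else {
    g <- ceiling(sqrt(nPlates))
    fIdx <- ((k - 1L) %% g) + 1L
    rIdx <- ((k - 1L) %/% g) + 1L
  }
  plates <- data.frame(
    plate_id = sprintf("P%02d", k),
    ext_fwd_id = pools$ext_fwd@id[fIdx],
    ext_fwd_seq = pools$ext_fwd@sequence[fIdx],
    ext_rev_id = pools$ext_rev@id[rIdx],
    ext_rev_seq = pools$ext_rev@sequence[rIdx])

  grid <- expand.grid(col = seq_len(cols), row = seq_len(rows),
                      plate = k)[, c("plate", "row", "col")]
  wellMap <- data.frame(
    plate_id = plates$plate_id[grid$plate],
    well = .wellName(grid$row, grid$col),
    row = grid$row, col = grid$col,
    int_fwd_id = rowBc$id[grid$row], int_fwd_seq = rowBc$seq[grid$row],
    int_rev_id = colBc$id[grid$col], int_rev_seq = colBc$seq[grid$col],
    ext_fwd_id = plates$ext_fwd_id[grid$plate],
    ext_fwd_seq = plates$ext_fwd_seq[grid$plate],
    ext_rev_id = plates$ext_rev_id[grid$plate],
    ext_rev_seq = plates$ext_rev_seq[grid$plate])
  new("PlateLayout", plates = plates, rowBarcodes = rowBc,
      colBarcodes = colBc, wellMap = wellMap, extDesign = extDesign)
}

setMethod("show", "PlateLayout", function(object) {
  cat(sprintf(
    "PlateLayout: %d plate(s) x %d rows x %d cols (%d wells), %s exterior design\n",
    nrow(object@plates), nrow(object@rowBarcodes),
    nrow(object@colBarcodes), nrow(object@wellMap), object@extDesign))
  cat(sprintf("  distinct barcodes: %d INT_FWD + %d INT_REV + %d EXT_FWD + %d EXT_REV\n",
              nrow(object@rowBarcodes), nrow(object@colBarcodes),
              length(unique(object@plates$ext_fwd_id)),
              length(unique(object@plates$ext_rev_id))))
})

#' @rdname buildLayout
#' @param layout A `PlateLayout`.
#' @export
wellMap <- function(layout) layout@wellMap

#' @rdname buildLayout
#' @export
plateTable <- function(layout) layout@plates

#' @rdname buildLayout
#' @export
nWells <- function(layout) nrow(layout@wellMap)

#' Distinct barcodes used by a layout
#'
#' @param layout A [PlateLayout-class].
#' @return data.frame with columns id, role, sequence over all distinct
#'   barcodes the layout consumes.
#' @export
layoutBarcodes <- function(layout) {
  wm <- layout@wellMap
  pieces <- rbind(
    data.frame(id = wm$int_fwd_id, role = "INT_FWD", sequence = wm$int_fwd_seq),
    data.frame(id = wm$int_rev_id, role = "INT_REV", sequence = wm$int_rev_seq),
    data.frame(id = wm$ext_fwd_id, role = "EXT_FWD", sequence = wm$ext_fwd_seq),
    data.frame(id = wm$ext_rev_id, role = "EXT_REV", sequence = wm$ext_rev_seq))
  unique(pieces)
}

#' Primer counts required by competing indexing schemes
#'
#' For N samples: sample-specific indexing needs N primers; unique dual
#' indexing needs 2N; combinatorial dual indexing needs the minimal r + c
#' with r x c >= N (about 2 sqrt(N)); the four-barcode row/column scheme
#' needs 2P + R + C for P plates of R x C wells; and the optimal
#' four-barcode scheme needs the minimal a + b + c + d with
#' a x b x c x d >= N (about 4 N^(1/4), by the rule of product).
#'
#' @param scheme One of `sample_specific`, `unique_dual`,
#'   `combinatorial_dual`, `four_barcode_rowcol`, `four_barcode_optimal`.
#' @param N Number of samples (>= 1).
#' @param P,R,C Geometry, required for `four_barcode_rowcol` only.
#' @return Integer primer count.
#' @examples
#' primersRequired("four_barcode_rowcol", 96, P = 1, R = 8, C = 12) # 22
#' primersRequired("combinatorial_dual", 96)                       # 20
#' @export
primersRequired <- function(scheme = c("sample_specific", "unique_dual",
                                       "combinatorial_dual",
                                       "four_barcode_rowcol",
                                       "four_barcode_optimal"),
                            N, P = NULL, R = NULL, C = NULL) {
  scheme <- match.arg(scheme)
  if (N < 1L) stop("N must be >= 1")
  N <- as.integer(N)
  switch(scheme,
    sample_specific = N,
    unique_dual = 2L * N,
    combinatorial_dual = {
      r <- seq_len(N)
      min(r + as.integer(ceiling(N / r)))
    },
    four_barcode_rowcol = {
      if (is.null(P) || is.null(R) || is.null(C))
        stop("parameter error: four_barcode_rowcol requires P, R and C")
      as.integer(2L * P + R + C)
    },
    four_barcode_optimal = .minSumProduct4(N))
}

## Minimal a+b+c+d over positive integers with a*b*c*d >= N.
## Enumerates canonical a <= b <= c and closes with the minimal feasible d.
.minSumProduct4 <- function(N) {
  best <- Inf
  aMax <- as.integer(ceiling(N^0.25)) + 1L
  for (a in seq_len(aMax)) {
    bMax <- as.integer(ceiling((N / a)^(1 / 3))) + 1L
    for (b in a:max(a, bMax)) {
      cMax <- as.integer(ceiling(sqrt(N / (a * b)))) + 1L
      for (cc in b:max(b, cMax)) {
        d <- max(cc, as.integer(ceiling(N / (a * b * cc))))
        best <- min(best, a + b + cc + d)
      }
    }
  }
  as.integer(best)
}

#' Write / read a plate-layout sample sheet
#'
#' TSV with one row per well and columns plate_id, well, row, col plus the
#' four barcode ids and sequences. `importSampleSheet` reconstructs the
#' full [PlateLayout-class]; export, import and re-export are
#' byte-identical.
#'
#' @param layout A [PlateLayout-class].
#' @param file TSV path.
#' @export
exportSampleSheet <- function(layout, file) {
  utils::write.table(layout@wellMap, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' @rdname exportSampleSheet
#' @export
importSampleSheet <- function(file) {
  wm <- utils::read.table(file, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  wm$well <- as.character(wm$well)
  rowBc <- unique(data.frame(row = wm$row, id = wm$int_fwd_id,
                             seq = wm$int_fwd_seq))
  rowBc <- rowBc[order(rowBc$row), c("id", "seq")]
  rownames(rowBc) <- NULL
  colBc <- unique(data.frame(col = wm$col, id = wm$int_rev_id,
                             seq = wm$int_rev_seq))
  colBc <- colBc[order(colBc$col), c("id", "seq")]
  rownames(colBc) <- NULL
  plates <- unique(wm[, c("plate_id", "ext_fwd_id", "ext_fwd_seq",
                          "ext_rev_id", "ext_rev_seq")])
  rownames(plates) <- NULL
  design <- if (anyDuplicated(plates$ext_fwd_id) ||
                anyDuplicated(plates$ext_rev_id)) "combinatorial"
            else "dual_unique"
  new("PlateLayout", plates = plates, rowBarcodes = rowBc,
      colBarcodes = colBc, wellMap = wm, extDesign = design)
}
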