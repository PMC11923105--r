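#' Hamming distance between two equal-length nucleotide strings
#'
#' @param a,b single character strings of equal length.
#' @return Integer count of mismatching positions.
#' @examples
#' hammingDistance("ACGTACGT", "ACGTACGA") # 1
#' @export
hammingDistance <- function(a, b) {
  if (length(a) != 1L || length(b) != 1L)
    stop("hammingDistance() compares two single strings")
  if (nchar(a) != nchar(b))
    stop("length mismatch: sequences must have equal length")
  sum(charToRaw(a) != charToRaw(b))
}

## Pairwise distances of every query against every pool sequence.
## Queries and pool must share one common length. Returns an
## n_query x n_pool integer matrix.
.hammingMatrix <- function(queries, pool) {
  if (!length(queries)) return(matrix(0L, 0L, length(pool)))
  w <- unique(nchar(c(queries, pool)))
  if (length(w) != 1L)
    stop("length mismatch: queries and pool must share one length")
  qm <- matrix(unlist(strsplit(queries, "", fixed = TRUE), use.names = FALSE),
               nrow = length(queries), byrow = TRUE)
  out <- matrix(0L, length(queries), length(pool))
  for (j in seq_along(pool)) {
    pj <- strsplit(pool[j], "", fixed = TRUE)[[1L]]
    out[, j] <- as.integer(rowSums(qm != matrix(pj, nrow = nrow(qm),
                                                ncol = w, byrow = TRUE)))
  }
  out
}

#' @importFrom Biostrings DNAStringSet reverseComplement
.rc <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

## "A01" style well names: row letters, zero-padded column numbers
.wellName <- function(row, col) {
  stopifnot(all(row >= 1L), all(row <= 26L))
  paste0(LETTERS[row], sprintf("%02d", col))
}

## Deterministic disambiguation of IUPAC codes: the lexicographically
## smallest compatible base. Used when a concrete amplicon molecule is
## built from a degenerate binding segment.
.IUPAC_FIRST <- c(A = "A", C = "C", G = "G", T = "T",
                  R = "A", Y = "C", S = "C", W = "A", K = "G", M = "A",
                  B = "C", D = "A", H = "A", V = "A", N = "A")

.disambiguate <- function(seq) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  paste(.IUPAC_FIRST[chars], collapse = "")
}

.randomDNA <- function(n, width) {
  vapply(seq_len(n),
         function(i) paste(sample(c("A", "C", "G", "T"), width,
                                  replace = TRUE), collapse = ""),
         character(1))
}

## Apply uniform per-base substitutions to a vector of equal-length reads.
## Each position independently mutates to one of the three other bases.
.addSubstitutions <- function(reads, rate) {
  if (rate <= 0 || !length(reads)) return(reads)
  w <- nchar(reads[1L])
  chars <- matrix(unlist(strsplit(reads, "", fixed = TRUE), use.names = FALSE),
                  nrow = length(reads), byrow = TRUE)
  hit <- which(stats::runif(length(chars)) < rate)
  if (length(hit)) {
    bases <- c("A", "C", "G", "T")
    repl <- vapply(chars[hit],
                   function(b) sample(setdiff(bases, b), 1L), character(1))
    chars[hit] <- repl
  }
  apply(chars, 1L, paste, collapse = "")
}
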