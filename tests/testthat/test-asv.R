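test_that("truncation clips to fixed lengths and rejects short pairs", {
  r1 <- strrep("A", 300); r2 <- strrep("C", 300)
  tr <- truncateReads(r1, r2)
  expect_identical(nchar(tr$r1), 180L)
  expect_identical(nchar(tr$r2), 120L)
  expect_false(any(tr$rejected))

  short <- truncateReads(strrep("A", 150), r2, fwdLen = 180)
  expect_true(short$rejected)
  expect_length(short$r1, 0L)

  exact <- truncateReads(strrep("A", 180), strrep("C", 120))
  expect_identical(exact$r1, strrep("A", 180))
  expect_identical(exact$r2, strrep("C", 120))
})

test_that("merging recovers the insert exactly from error-free truncated pairs", {
  set.seed(21)
  insert <- paste(sample(c("A", "C", "G", "T"), 254, TRUE), collapse = "")
  r1 <- substr(insert, 1, 180)
  rc <- function(x) as.character(
    Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  r2 <- rc(substr(insert, 135, 254))      # last 120 nt, reverse strand
  merged <- mergePairs(r1, r2)
  expect_identical(merged, insert)
  expect_identical(nchar(merged), 254L)   # overlap 180 + 120 - 254 = 46

  # deterministically non-overlapping pair
  no <- mergePairs(strrep("AC", 60), rc(strrep("GT", 60)))
  expect_true(is.na(no))

  # r1 identical to rc(r2): full-length overlap
  full <- mergePairs(r1, rc(r1), minOverlap = 12)
  expect_identical(full, r1)
})

test_that("overlap mismatches within tolerance take the forward base", {
  set.seed(22)
  insert <- paste(sample(c("A", "C", "G", "T"), 254, TRUE), collapse = "")
  r1 <- substr(insert, 1, 180)
  rc <- function(x) as.character(
    Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  tail120 <- substr(insert, 135, 254)
  pos <- 10L  # inside the 46 nt overlap (positions 1..46 of the tail)
  mutated <- tail120
  substr(mutated, pos, pos) <- setdiff(c("A", "C", "G", "T"),
                                       substr(tail120, pos, pos))[1]
  r2 <- rc(mutated)
  expect_true(is.na(mergePairs(r1, r2, maxMismatch = 0)))
  merged <- mergePairs(r1, r2, maxMismatch = 1)
  expect_identical(merged, insert)  # R1 base wins in the overlap
})

test_that("dereplication collapses exact duplicates and conserves reads", {
  s1 <- strrep("ACGT", 10); s2 <- sub("^A", "C", s1)
  tab <- dereplicate(list(A01 = rep(s1, 10), A02 = c(rep(s1, 3), rep(s2, 4)),
                          A03 = character(0)))
  m <- asvCounts(tab)
  expect_identical(dim(m), c(2L, 3L))
  expect_identical(as.integer(colSums(m)), c(10L, 7L, 0L))
  seqs <- asvSequences(tab)
  expect_identical(unname(seqs[1]), s1)  # most abundant first
  expect_identical(sum(m), 17L)
  expect_true(all(m[, "A03"] == 0L))
})

test_that("representative calls apply inclusive read and proportion thresholds", {
  counts <- matrix(c(15L, 85L,   # w1: 0.15 of 100 -> in
                     14L, 86L,   # w2: fails read threshold
                     20L, 230L,  # w3: 0.08 of 250 -> fails proportion
                     15L, 135L), # w4: exactly 0.10 of 150 -> in
                   nrow = 2,
                   dimnames = list(c("ASV0001", "ASV0002"),
                                   c("w1", "w2", "w3", "w4")))
  tab <- AsvCountTable(counts, sequences = c(strrep("A", 50), strrep("C", 50)))
  calls <- representativeCalls(callRepresentative(tab))
  a1 <- calls[calls$asv_id == "ASV0001", ]
  expect_identical(sort(a1$well), c("w1", "w4"))
  expect_true(all(calls$asv_id[calls$well == "w2"] != "ASV0001"))
  expect_true(all(calls$asv_id[calls$well == "w3"] != "ASV0001"))
  # the dominant ASV is representative everywhere
  expect_identical(sort(calls$well[calls$asv_id == "ASV0002"]),
                   c("w1", "w2", "w3", "w4"))
})

test_that("zero-total wells have no representatives and counts bound the calls", {
  counts <- matrix(c(0L, 0L, 200L, 100L), nrow = 2,
                   dimnames = list(c("ASV0001", "ASV0002"), c("empty", "full")))
  tab <- AsvCountTable(counts, c(strrep("A", 40), strrep("G", 40)))
  calls <- callRepresentative(tab)
  expect_identical(sum(representativeCalls(calls)$well == "empty"), 0L)
  # per-well representative count can never exceed floor(1 / minProp)
  perWell <- table(representativeCalls(calls)$well)
  expect_true(all(perWell <= 10L))
})

test_that("raising either threshold never adds a representative", {
  rt <- roundTripFixture()
  base <- representativeCalls(callRepresentative(rt$asv$table))
  stricter <- list(callRepresentative(rt$asv$table, minReads = 30),
                   callRepresentative(rt$asv$table, minProp = 0.3))
  key <- function(cl) paste(cl$well, cl$asv_id)
  for (s in stricter)
    expect_true(all(key(representativeCalls(s)) %in% key(base)))
})

test_that("the pipeline recovers the planted well-taxon map end to end", {
  rt <- roundTripFixture()
  calls <- representativeCalls(rt$asv$calls)
  colony <- rt$assignment[!rt$assignment$is_control, ]
  keys <- paste0(colony$plate_id, ":", colony$well)
  perWell <- table(factor(calls$well, levels = keys))
  expect_true(all(perWell == 1L))
  tplSeq <- as.character(rt$templates)
  asvSeq <- asvSequences(rt$asv$table)
  called <- asvSeq[calls$asv_id[match(keys, calls$well)]]
  expect_identical(unname(called), unname(tplSeq[colony$template_id]))
  # dereplication conserves merged reads
  expect_identical(sum(asvCounts(rt$asv$table)),
                   sum(rt$asv$mergeStats$merged))
})

test_that("well summaries tally categories and fractions correctly", {
  counts <- matrix(0L, nrow = 3, ncol = 4,
                   dimnames = list(sprintf("ASV%04d", 1:3),
                                   c("one", "two", "none", "ctrl")))
  counts[1, "one"] <- 200L
  counts[1:2, "two"] <- 100L           # 50/50 split at 200 reads
  tab <- AsvCountTable(counts, c(strrep("A", 30), strrep("C", 30),
                                 strrep("G", 30)))
  calls <- callRepresentative(tab)
  sm <- summarizeWells(calls, controls = "ctrl")
  expect_identical(sm@tallies, c(`0` = 1L, `1` = 1L, `2` = 1L, `3+` = 0L))
  expect_equal(sm@fractionAtLeastOne, 2 / 3)
  expect_equal(sm@fractionExactlyOne, 1 / 3)
  expect_identical(unname(sm@controlTallies["0"]), 1L)

  allEmpty <- summarizeWells(callRepresentative(
    AsvCountTable(matrix(0L, 1, 2,
                         dimnames = list("ASV0001", c("a", "b"))),
                  strrep("T", 30))))
  expect_identical(allEmpty@tallies, c(`0` = 2L, `1` = 0L, `2` = 0L,
                                       `3+` = 0L))
})

test_that("count tables round-trip through TSV and export FASTA", {
  rt <- roundTripFixture()
  d <- withr::local_tempdir()
  f <- file.path(d, "counts.tsv")
  writeCountTable(rt$asv$table, f)
  back <- readCountTable(f)
  expect_identical(asvCounts(back), asvCounts(rt$asv$table))
  expect_identical(asvSequences(back), asvSequences(rt$asv$table))
  fa <- file.path(d, "asv.fasta")
  writeAsvFasta(back, fa)
  seqs <- Biostrings::readDNAStringSet(fa)
  expect_identical(unname(as.character(seqs)), unname(asvSequences(back)))
  expect_identical(names(seqs), names(asvSequences(back)))
})
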