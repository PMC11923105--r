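test_that("synthetic templates honour length, divergence and determinism", {
  one <- generateTemplates(1, insertLength = 254, seed = 1)
  expect_length(one, 1L)
  expect_identical(Biostrings::width(one), 254L)

  same <- generateTemplates(2, divergence = 0, seed = 3)
  expect_identical(as.character(same[[1]]), as.character(same[[2]]))

  div <- generateTemplates(8, divergence = 0.1, seed = 2)
  s <- as.character(div)
  for (i in 1:7) for (j in (i + 1):8) {
    ident <- 1 - hammingDistance(s[i], s[j]) / 254
    expect_lte(ident, 0.95)
  }
  again <- generateTemplates(8, divergence = 0.1, seed = 2)
  expect_identical(as.character(div), as.character(again))
})

test_that("amplicon length is the sum of its segments and barcodes match the layout", {
  fx <- plateFixture()
  cfg <- segmentConfig()
  tpl <- generateTemplates(1, seed = 4)
  amp <- buildAmplicon(tpl, "B05", fx$layout)
  expect_identical(nchar(ampliconSequence(amp)),
                   sum(nchar(amp@segments)))
  expect_identical(unname(nchar(amp@segments)),
                   c(nchar(cfg@p5Adapter), 8L, nchar(cfg@nexteraFwd), 8L,
                     nchar(cfg@bindingFwd), 254L, nchar(cfg@bindingRev),
                     8L, nchar(cfg@nexteraRev), 8L, nchar(cfg@p7Adapter)))
  wm <- wellMap(fx$layout)
  w <- wm[wm$well == "B05", ]
  bcs <- ampliconBarcodes(amp)
  expect_identical(unname(bcs["int_fwd"]), w$int_fwd_seq)
  expect_identical(unname(bcs["int_rev"]), w$int_rev_seq)
  expect_identical(unname(bcs["ext_fwd"]), w$ext_fwd_seq)
  expect_identical(unname(bcs["ext_rev"]), w$ext_rev_seq)
  # wells of one row share the interior-forward barcode segment
  ampB11 <- buildAmplicon(tpl, "B11", fx$layout)
  expect_identical(amp@segments["int_fwd_bc"], ampB11@segments["int_fwd_bc"])
  expect_error(buildAmplicon(tpl, "Z99", fx$layout), "lookup error")
})

test_that("an unperturbed run emits the expected pairs with valid exterior indices", {
  fx <- plateFixture()
  tpl <- generateTemplates(2, seed = 5)
  asn <- makeAssignment(fx$layout, names(tpl), nControls = 0, seed = 6)
  run <- simulateRun(fx$layout, asn, tpl, readsPerWell = 10, seed = 7)
  expect_length(run@r1, 960L)
  expect_length(run@r2, 960L)
  ext <- sub("^.*plate_ext:", "", names(run@r1))
  valid <- paste0(fx$layout@plates$ext_fwd_seq, "+",
                  fx$layout@plates$ext_rev_seq)
  expect_true(all(ext %in% valid))
  expect_identical(sum(run@truth$hopped), 0L)
})

test_that("identical seeds give byte-identical FASTQ output", {
  fx <- plateFixture()
  tpl <- generateTemplates(2, seed = 5)
  asn <- makeAssignment(fx$layout, names(tpl), nControls = 1, seed = 6)
  d1 <- withr::local_tempdir()
  a <- simulateRun(fx$layout, asn, tpl, readsPerWell = 5,
                   subErrorRate = 0.01, seed = 9,
                   outPrefix = file.path(d1, "a"))
  b <- simulateRun(fx$layout, asn, tpl, readsPerWell = 5,
                   subErrorRate = 0.01, seed = 9,
                   outPrefix = file.path(d1, "b"))
  expect_identical(readLines(file.path(d1, "a_R1.fastq")),
                   readLines(file.path(d1, "b_R1.fastq")))
  expect_identical(readLines(file.path(d1, "a_R2.fastq")),
                   readLines(file.path(d1, "b_R2.fastq")))
  c <- simulateRun(fx$layout, asn, tpl, readsPerWell = 5,
                   subErrorRate = 0.01, seed = 10)
  expect_false(identical(unname(a@r1), unname(c@r1)))
})

test_that("hop_rate = 1 replaces exactly one exterior index of every read", {
  pools <- generateBarcodePools(plates = 2, seed = 21)
  lay <- buildLayout(2, 8, 12, pools)
  tpl <- generateTemplates(2, seed = 5)
  asn <- makeAssignment(lay, names(tpl), nControls = 0, seed = 6)
  run <- simulateRun(lay, asn, tpl, readsPerWell = 3, hopRate = 1, seed = 8)
  expect_true(all(run@truth$hopped == 1L))
  wm <- wellMap(lay)
  key <- paste(wm$plate_id, wm$well)
  obs <- regmatches(names(run@r1),
                    regexec("plate_ext:([ACGT]+)\\+([ACGT]+)", names(run@r1)))
  truthIdx <- match(paste(run@truth$plate_id, run@truth$well), key)
  nSwapped <- mapply(function(m, i) {
    (m[2] != wm$ext_fwd_seq[i]) + (m[3] != wm$ext_rev_seq[i])
  }, obs, truthIdx)
  expect_true(all(nSwapped == 1L))
  # dual-unique design: every hopped pair is absent from the layout
  pairs <- vapply(obs, function(m) paste0(m[2], "+", m[3]), character(1))
  valid <- paste0(lay@plates$ext_fwd_seq, "+", lay@plates$ext_rev_seq)
  expect_false(any(pairs %in% valid))
})

test_that("observed substitution rate is binomially consistent with the setting", {
  fx <- noisyRunFixture()
  run0 <- memo("noisy0", function() {
    tpl <- generateTemplates(4, seed = 105)
    asn <- makeAssignment(fx$layout, names(tpl), nControls = 0, seed = 106)
    simulateRun(fx$layout, asn, tpl, readsPerWell = 10, subErrorRate = 0,
                seed = 107)
  })
  nPos <- sum(nchar(fx$run@r1)) + sum(nchar(fx$run@r2))
  mism <- sum(vapply(seq_along(fx$run@r1), function(i)
    hammingDistance(unname(fx$run@r1[i]), unname(run0@r1[i])) +
    hammingDistance(unname(fx$run@r2[i]), unname(run0@r2[i])), integer(1)))
  p <- 0.01
  sigma <- sqrt(nPos * p * (1 - p))
  expect_lt(abs(mism - nPos * p), 3 * sigma)
})

test_that("hopping a single-plate run requires an explicit hop pool", {
  fx <- plateFixture()
  tpl <- generateTemplates(1, seed = 5)
  asn <- makeAssignment(fx$layout, names(tpl), nControls = 0, seed = 6)
  expect_error(simulateRun(fx$layout, asn, tpl, readsPerWell = 1,
                           hopRate = 0.1, seed = 1), "config error")
  foreign <- generateBarcodePools(plates = 3, seed = 77)
  run <- simulateRun(fx$layout, asn, tpl, readsPerWell = 5, hopRate = 1,
                     seed = 2,
                     hopPool = list(ext_fwd = foreign$ext_fwd@sequence,
                                    ext_rev = foreign$ext_rev@sequence))
  expect_true(all(run@truth$hopped == 1L))
})

test_that("assignments referencing unknown templates are rejected", {
  fx <- plateFixture()
  tpl <- generateTemplates(2, seed = 5)
  asn <- makeAssignment(fx$layout, c("nope"), nControls = 0, seed = 6)
  expect_error(simulateRun(fx$layout, asn, tpl, readsPerWell = 1, seed = 1),
               "config error")
})
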