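## Shared fixtures, built once per test run and memoized.

.fx <- new.env(parent = emptyenv())

memo <- function(key, build) {
  if (is.null(.fx[[key]])) .fx[[key]] <- build()
  .fx[[key]]
}

## Single 96-well plate with default pools.
plateFixture <- function() memo("plate", function() {
  pools <- generateBarcodePools(seed = 101)
  list(pools = pools, layout = buildLayout(1, 8, 12, pools))
})

## The study-scale round trip: 93 colony wells over 8 synthetic taxa,
## 3 empty controls, 200 reads/well, no errors, no hopping.
roundTripFixture <- function() memo("roundtrip", function() {
  fx <- plateFixture()
  templates <- generateTemplates(8, insertLength = 254, divergence = 0.05,
                                 seed = 102)
  assignment <- makeAssignment(fx$layout, names(templates), nControls = 3,
                               seed = 103)
  run <- simulateRun(fx$layout, assignment, templates, readsPerWell = 200,
                     seed = 104)
  demux <- demultiplex(run@r1, run@r2, fx$layout)
  list(layout = fx$layout, templates = templates, assignment = assignment,
       run = run, demux = demux, asv = asvPipeline(demux))
})

## A small noisy run (substitution errors, no hopping) on the same plate.
noisyRunFixture <- function() memo("noisy", function() {
  fx <- plateFixture()
  templates <- generateTemplates(4, seed = 105)
  assignment <- makeAssignment(fx$layout, names(templates), nControls = 0,
                               seed = 106)
  run <- simulateRun(fx$layout, assignment, templates, readsPerWell = 10,
                     subErrorRate = 0.01, seed = 107)
  list(layout = fx$layout, run = run)
})

## Independent oracle for the primer-count minimizations: layered dynamic
## programme for "minimal sum of k positive integers whose product is at
## least N", computed bottom-up over all N up to nMax. Level k=2 is the
## combinatorial-dual optimum, k=4 the optimal four-barcode count.
minSumOracle <- function(nMax, k) {
  f <- seq_len(nMax)              # k = 1: a single factor >= N
  for (level in seq_len(k - 1L)) {
    g <- integer(nMax)
    for (n in seq_len(nMax)) {
      a <- seq_len(n)
      g[n] <- min(a + f[ceiling(n / a)])
    }
    f <- g
  }
  f
}

## Exhaustive pairwise minimum Hamming distance of a BarcodeSet.
minPairwiseDistance <- function(set) {
  s <- unname(barcodeSeqs(set))
  if (length(s) < 2L) return(Inf)
  min(apply(utils::combn(length(s), 2L), 2L,
            function(p) hammingDistance(s[p[1L]], s[p[2L]])))
}

wellKeys <- function(assignment, controlsOnly = FALSE) {
  a <- if (controlsOnly) assignment[assignment$is_control, ] else assignment
  paste0(a$plate_id, ":", a$well)
}
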