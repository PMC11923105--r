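---
title: "Four-barcode combinatorial indexing: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Four-barcode combinatorial indexing: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(platemux)
```

# The indexing model

Every reaction receives four primers, each carrying an 8 nt index.
Interior primers anneal to the target locus (515F/806R-style binding
segments for the ~254 nt 16S V4 region) and their indices are read
inline as the first 8 nt of R1 and R2. Exterior primers carry the
P5/P7 flow-cell adapters and prime on the Nextera-style overlap of the
interior product; their i5/i7-style indices are read by the sequencer
and modelled here as a `plate_ext:<FWD>+<REV>` field in the read
header. A well is encoded combinatorially: the row's interior-forward
index × the column's interior-reverse index × the plate's exterior
pair.

For `N` samples the competing schemes need:

| scheme | primers | minimization |
|---|---|---|
| sample-specific | `N` | — |
| unique dual | `2N` | — |
| combinatorial dual | `≈ 2√N` | min `r + c`, `r·c ≥ N` |
| four-barcode row/column | `2P + R + C` | geometry fixed |
| four-barcode optimal | `≈ 4·N^(1/4)` | min `a+b+c+d`, `a·b·c·d ≥ N` |

`primersRequired()` implements the exact integer minimizations; the
closed forms are asymptotic readings (the four-factor optimum follows
from the rule of product: capacity is the product of the per-primer-type
option counts, maximized when all four are equal). Note the four-factor
optimum only undercuts the two-factor one from `N ≥ 13`: below that,
paying four factors of at least 1 each costs more than two.

## Index hopping and dual uniqueness

Index hopping swaps one exterior index of a read for another present in
the pool. Under the default `dual_unique` exterior design no exterior
barcode recurs across plates, so a read with one swapped index carries a
pair used by *no* plate: the demultiplexer flags it `HOPPED` and drops
it. Under a `combinatorial` exterior design (plates on a grid, exterior
barcodes reused along grid rows/columns) the swapped pair can be another
plate's valid pair and the read is silently misassigned. Both designs
are constructible with `buildLayout()` so the contrast is directly
measurable against the simulator's ground truth; the layout validity
check enforces no-reuse only under `dual_unique`, which is the
recommended design.

# Tunable parameters

| parameter | default | unit | rationale |
|---|---|---|---|
| barcode length | 8 | nt | index capacity 4^8 per role, read-length cost negligible |
| barcode min Hamming distance | 3 | subst. | one sequencing error can never reach another barcode within tolerance 1 |
| barcode homopolymer cap | 3 | nt | avoids synthesis/sequencing pathologies |
| demux `maxMismatch` | 1 | subst. per barcode | safe under distance-3 pools; ties (only possible with user pools of distance < 3) are `AMBIGUOUS`, never guessed |
| insert length | 254 | nt | 16S V4 target length |
| read length | 300 | nt | 300×2 amplicon chemistry |
| truncation | 180 / 120 | nt (fwd/rev) | post-trim truncation; 180+120−254 leaves a 46 nt merge overlap |
| merge `minOverlap` | 12 | nt | conventional paired-end merge floor |
| merge `maxMismatch` | 0 | subst. in overlap | strict by default; R1 base wins when relaxed (deterministic tie-break) |
| representative `minReads` | 15 | reads | absolute noise floor |
| representative `minProp` | 0.1 | fraction of well total | relative floor; both thresholds inclusive (`≥`) — "passing a minimum" is read as attaining it |

The segment defaults (P5/P7 adapters, overlap regions) are conventional
Nextera-style strings; they parameterize geometry only and are not a
vendor reference. IUPAC degeneracy is allowed in binding segments only;
barcodes are strict A/C/G/T so matching is unambiguous.

# The simulator: what it emulates, what it does not

`generateTemplates()` draws a random ancestor and mutates each taxon
independently at `divergence/2` per site, so pairwise divergence is
approximately `divergence`. `simulateRun()` builds each well's amplicon
(degenerate binding bases resolved to the lexicographically smallest
compatible base, since a physical molecule is concrete), reads 300 nt
from each end starting at the interior barcodes, applies uniform
per-base substitutions, and hops each read's exterior pair with
probability `hopRate` (a fair coin picks the side; the replacement is
drawn uniformly from the other candidates in `hopPool`, defaulting to
the layout's own exterior barcodes). Hopping a single-plate run
requires an explicit foreign `hopPool` — there is no other barcode to
swap in otherwise.

Deliberately absent: indels, quality-dependent and position-dependent
error, chimeras, amplification bias, real 16S conservation structure,
and separate I1/I2 index FASTQ files (the header field stands in for
sequencer-side index reads). Passing tests therefore demonstrate the
correctness of the bookkeeping — layout arithmetic, demultiplexing,
thresholding — under a controlled error model, not performance on real
MiSeq data, where quality filtering and denoising do additional work.

# ASV calling without a denoiser

Reads are truncated to fixed lengths (pairs with a too-short mate are
rejected), merged by the maximal suffix–prefix overlap of R1 against
reverse-complemented R2, and dereplicated *exactly*: every distinct
merged sequence is one ASV. This replaces error-model denoising by
design — with nonzero error rates, errors surface as low-count
satellite ASVs, which the 15-read / 0.10-proportion representative
thresholds absorb. Users with real data can run any denoiser upstream
and load its table via `readCountTable()`; the representative and
summary logic is agnostic to where counts came from.

`summarizeWells()` reports the fraction of wells with at least one
representative (amplification success) and with exactly one (single
clear genotype), excluding annotated controls from denominators —
controls are identified by annotation, never inferred. A well whose
multiple representatives reflect one organism (e.g. intragenomic 16S
variation) counts as one only with external adjudication, which is out
of scope here; the summary reports the representative counts as
computed.

# Numerical and design choices

- **Determinism.** Every stochastic step takes a seed; identical seeds
  give byte-identical FASTQ. ASV ids are assigned by decreasing total
  abundance with sequence as tie-break.
- **Degenerate inputs.** Zero-read wells produce all-zero columns and
  no representatives; empty barcode pools and infeasible barcode
  requests (e.g. distance > length) raise capacity errors before any
  work.
- **Conservative demultiplexing.** A read whose exterior pair matches a
  plate but whose interior pair resolves to no well is `NO_MATCH`, not
  assigned to the nearest well; statuses partition the input exactly.
- **Trimming is positional.** Barcode and binding segments are removed
  by fixed length — primer-anchored reads have fixed geometry, so no
  alignment is needed.
- **Cost model.** Components accrue per sample, per plate
  (`⌈n/wells⌉` plates amortized over `n`), or per pool (divided by
  `n`). Per-colony cost is non-increasing within a plate and across
  full-plate multiples, but jumps when a partial plate opens — an
  honest property of ceiling amortization. The shipped YAML prices are
  placeholders; conclusions about real workflows require your own
  quotes.
- **Problem sizes.** The test suite exercises one 96-well plate at 200
  reads/well (18,600 pairs) for the clean round trip, smaller runs for
  error and hopping properties, and verifies the primer minimizations
  against an independent dynamic-programming oracle for all N ≤ 2000.

# Limitations

Exact dereplication over-splits under high error rates where a denoiser
would not; the hopping model swaps exactly one index per hopped read;
quality strings are constant; and the simulator's uniform templates make
demultiplexing easier than real mixed-quality libraries. The package
measures and demonstrates the *design properties* of four-barcode
indexing; analysing a real run end to end additionally needs quality
filtering and (optionally) denoising upstream of the count table.
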