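---
title: "Filling repeat-masked gaps in alignment chains: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Filling repeat-masked gaps in alignment chains: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chaingapfill)
```

## The model

A pairwise genome alignment chain (UCSC chain format) is a co-linear list
of ungapped aligned blocks between a reference (target) interval and a
query interval; between consecutive blocks, `dt` target bases and `dq`
query bases are unaligned. Whole-genome aligners do not start local
alignments from seeds inside soft-masked (lowercase) repeats, so an
orthologous repeat pair whose flanks are too diverged to host a nearby
seed shows up as an interior chain gap with `dt` and `dq` both roughly the
size of the repeat.

The method implemented here re-examines such gaps under three premises:

* a gap bounded by aligned blocks on both sides pins down the orthologous
  context, so seeding inside it — repeats included — is safe;
* restricting attention to gaps of at most 20 kb keeps the chance of
  aligning non-orthologous repeat copies low;
* any new alignment must justify itself by score, both locally (HSP and
  gapped thresholds) and as a combined mini chain (insertion threshold).

The pipeline per gap is: fetch both fragments in chain orientation with
masking removed → seed-and-extend local alignment → combine the local
alignments into the best co-linear mini chain under piecewise-linear gap
costs → insert the mini chain if it scores at least the insertion
threshold → recompute the chain score from sequence.

## Parameters

| parameter | default | units | role |
|---|---|---|---|
| `min_gap`, `max_gap` | 30, 20000 | bp | both `dt` and `dq` must fall in this inclusive range for a gap to qualify; a gap whose other side is tiny has nothing to align against, and very large gaps raise the paralogy risk |
| `min_chain_score` | 25000 | score | chains must score *strictly above* this to be processed; low-scoring chains are too unreliable a context |
| `min_mini_score` | 5000 | score | a mini chain is inserted only when its score is *at least* this |
| `K` | 2000 (fill), 2400 (first pass) | score | minimum ungapped (HSP) score; the fill stage is run slightly more sensitively |
| `L` | 3000 | score | minimum gapped alignment score |
| `Y` | 9400 | score | Y-drop: a gapped extension abandons any cell whose best score falls more than `Y` below the best seen |
| `gap_open`, `gap_extend` | 400, 30 | score | affine gap penalties; a gap of length `n` costs `400 + 30 n` |
| `x_drop` | 10 × max diagonal entry (910) | score | ungapped extension stops when the running score drops this far below its maximum; it truncates extensions but does not change threshold semantics |
| `k` | 12 | bp | contiguous exact seed length |
| `seed_cap` | 50000 | count | seed-explosion guard per gap (deterministic subsample, seeded from chain id, block index and `rng_seed`) |
| `H` | 2000 | score | accepted in configurations for compatibility, unused: no inner-alignment stage is implemented |

The substitution matrix is the HOXD70 matrix (the standard default for
mammalian DNA alignment), shipped as an editable score file in
`inst/extdata/hoxd70.txt`; alternative matrices can be supplied in the
same LASTZ score-file syntax via `read_score_file()`.

Connection costs in mini-chain construction and chain rescoring use the
UCSC axtChain "loose" linear-gap schedule (`inst/extdata/loose_gap_costs.txt`),
transcribed verbatim: a table of breakpoints with one-sided and two-sided
costs, interpolated linearly between breakpoints and extrapolated with
the last slope. Interpolation uses integer floor division, so all chain
arithmetic — column scores, gap costs, chain and mini-chain scores — stays
in exact integers, which makes the threshold comparisons (`> 25000`,
`≥ 5000`) reproducible to the digit.

```{r gap-costs}
tab <- default_gap_costs()
gap_cost(tab, 0, 0)     # zero gap costs nothing
gap_cost(tab, 7, 0)     # floor-interpolated between breakpoints 3 and 11
gap_cost(tab, 100, 40)  # two-sided gaps use the "both" schedule at dt+dq
```

## Numerical choices in the aligner

**Seeding.** Contiguous exact 12-mers, found by hashing; both k-mers must
be `N`-free. This is a simpler seed than the spaced patterns genome
aligners use and is the package's documented stand-in; at gap scale (≤20
kb) the sensitivity loss is negligible because orthologous copies at the
divergences of interest offer many exact 12-mers. When a repeat-dense gap
produces more matches than `seed_cap`, a uniform subsample is kept; the
subsample is drawn with a dedicated xorshift generator seeded from the
gap's identity, so runs are reproducible and independent of R's RNG
state.

**Ungapped stage.** Each seed is extended along its diagonal in both
directions under the X-drop rule; the maximal-scoring segment containing
the seed is kept if it reaches `K`. Seeds falling inside a previous
extension on the same diagonal are skipped.

**Gapped stage.** Each HSP is anchored at its maximum-scoring point (the
first column attaining the maximal running prefix score) and extended
leftward and rightward independently by banded affine dynamic programming;
the band is whatever the Y-drop rule keeps alive, roughly
`2·Y/gap_extend ≈ 600` columns at the defaults. Traceback prefers the
diagonal over a gap in the query over a gap in the reference, and among
equal-scoring endpoints the earliest (smallest extension) is kept, so
output is deterministic byte for byte. HSPs covered by an
already-extended alignment are not re-extended. Gap-to-gap state
transitions are not allowed (a deletion directly followed by an insertion
costs two gap opens), matching the usual three-state affine recurrence.

**Case and N.** The fill stage uppercases fragments before aligning
(masking removed); any column involving `N` scores the worst matrix entry
and `N` never seeds. In the masked regime (`masked = TRUE`, used by the
simulator's first pass) lowercase bases are treated like `N`: they
neither seed nor score above the worst entry.

**What the heuristic guarantees.** A reported score never exceeds the
affine-gap Smith–Waterman optimum of the fragment pair. With unbounded
Y-drop and every HSP tried, the best reported score attains that optimum
whenever some HSP anchor lies on an optimal path — the test suite verifies
exact agreement with a brute-force Smith–Waterman oracle on hundreds of
seeded random pairs. With the default deduplication a slightly lower
score is possible when the first (highest-scoring) HSP anchors off the
optimal path; this mirrors how production seed-and-extend aligners trade
exactness for speed.

**Orientation.** Fragments are aligned only in the orientation implied by
the parent chain: a filled block must stay co-linear with its flanks, so
searching the reverse strand inside a gap would be meaningless.

## Mini-chain construction

Local alignments from one gap are chained by dynamic programming over
fragments ordered by start coordinate, maximising cumulative score minus
connection gap costs. When a successor overlaps its best predecessor on
either genome, the successor is trimmed from its start by whole alignment
columns until it clears the predecessor, and its score is scaled by the
kept fraction of aligned columns (floored to an integer) — the signature
has no sequence access, so the reduction is proportional rather than
recomputed. Only the single best mini chain per gap is returned and it is
inserted whole; gaps are processed independently, so results do not
depend on processing order. Newly created gaps (the subdivided remainder
on either side of an insertion) are not re-examined: filling is one pass
over the original gaps.

Two prints of the insertion bookkeeping: the flanking `dt`/`dq` are
recomputed so span sums are conserved (gaps are subdivided, never
resized), and a new block flush against a neighbour on both genomes is
merged into it.

## The simulator

`generate_dataset()` produces the study conditions the package is tested
under: a 1 Mb ancestor with i.i.d. uniform background; three repeat
families with 300, 800 and 1500 bp consensi and 40, 25 and 15 copies
(≈5.5% of the genome, planted non-overlapping with ≥800 bp unmasked
spacers so first-pass seeds exist between copies); 8% per-copy divergence
from consensus; two descendant lineages evolved independently with 10%
per-site substitutions and 0.5% indels of geometric length (mean 3 bp).
Orthologous repeat copies therefore differ by ≈19% — squarely in the range
where they align well once seeded. A single RNG stream seeded once drives
every draw, so datasets are byte-reproducible.

**The first-pass regime.** The first-pass chain is computed with
`masked = TRUE`: soft-masked bases neither seed nor score above the worst
matrix entry. Treating masked bases as unalignable — not merely unseedable
— is a deliberate design choice. In a short co-linear simulation the
unmasked flanks are dense with seeds, so an extension-permissive first
pass would simply run through every high-identity repeat and leave
nothing to fill; real genomes produce repeat gaps because diverged or
rearranged flanks starve the repeat of nearby seeds, a circumstance a
desk-scale co-linear simulator cannot reproduce directly. Hard-stopping
extensions at mask boundaries recreates the *consequence* of that
circumstance — chain gaps that coincide with planted repeats — while
keeping the invariant that no alignment is ever seeded inside masked
sequence. With ≥300 bp copies the cost of crossing a masked repeat
(roughly `60·length + 800` through double gaps, or `125·length`
diagonally) always exceeds `Y = 9400`, so extensions stop at repeat
boundaries.

**What the simulator does not emulate.** No paralogous placement of
repeat copies into corresponding positions (so the precision proxy cannot
probe paralogous misalignment, only alignment outside orthologous
regions); no rearrangements or inversions (the filler assumes
co-linearity); no transposon biology — superfamily structure, target-site
duplications, nested insertions; no GC or substitution-rate
heterogeneity; no assembly artifacts. Passing tests therefore demonstrate
that the machinery recovers orthologous repeat alignments it was starved
of, with exact score arithmetic and conservation of everything it does
not touch — they do not quantify false-positive rates in paralog-rich
real genomes, where the chain-score and gap-size filters carry that
burden.

## Degenerate inputs and edge rules

* Chains with a `-` target strand are a parse error (UCSC convention puts
  the strand flip on the query); query `-` strand coordinates follow the
  chain convention and are resolved by strand-aware fetching.
* Fragments shorter than the seed length yield no seeds — an empty
  result, not an error.
* An empty gap fragment cannot occur (gap bounds are ≥ `min_gap`), but
  `align_region("", x)` returns an empty list.
* A mini chain mapping outside its gap is an internal error and is
  asserted, never silently clipped.
* `cost(0,0) = 0` by definition; negative gap sizes are rejected.
* Ties everywhere (equal DP scores, equal chain scores) resolve to the
  earliest candidate in deterministic sort order.

## Problem sizes in the test suite

The unit suite exercises the aligner oracles on ≤60 bp pairs (hundreds of
seeded cases against a brute-force Smith–Waterman), chaining on ≤6
fragments against exhaustive enumeration, format round-trips on 1000+
fuzzed records, and conservation and recovery end to end on simulated
datasets of 30–150 kb; the acceptance checks run the full default 1 Mb
simulation. These sizes were chosen so the whole suite completes in a few
minutes while every code path, including the genome-scale first pass,
is exercised at its production parameters.

## Known limitations

* The LASTZ inner-alignment stage (`H`) is not implemented; `H` is parsed
  and ignored.
* Only the best mini chain per gap is inserted; secondary co-linear
  alignments within one gap are discarded.
* One pass per original gap: insertions are not recursively re-examined.
* The mini-chain score used for the ≥5000 filter is defined by this
  package's trimming rule (proportional, floor); other chainers may
  score trimmed connections slightly differently.
* 2bit/nib sequence containers, net files and MAF output are out of
  scope; sequences are FASTA (plain or gzipped).
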