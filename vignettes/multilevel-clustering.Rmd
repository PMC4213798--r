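---
title: "Multi-level threshold clustering: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-level threshold clustering: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mlclust)
```

## The problem

Threshold clustering asks for groups of sequences such that similar
sequences (percent identity at or above a threshold *t*) end up together.
The exact answer — the connected components of the *threshold graph*, whose
edges join pairs with similarity ≥ *t* — requires, in the worst case, all
N(N−1)/2 pairwise alignments. For reference databases of 10^5–10^6 barcode
sequences that matrix is unaffordable in both time and memory, yet it is
precisely how species-level OTU delimitation of markers such as the fungal
ITS region is defined in practice.

`mlclust` implements a family of algorithms that approximate the
connected-component answer while skipping most comparisons:

* **GC** (greedy clustering, the UCLUST/CD-HIT scheme): one pass over the
  length-sorted input; each sequence joins the first established
  representative within threshold, or founds a new cluster. O(N·m)
  comparisons for *m* clusters, but accuracy suffers because membership is
  decided by a single representative comparison.
* **CCBC**: the exact connected components, at full-matrix cost (its cost
  fraction *f* = 1 by definition).
* **MLC1**: cut the input into *K* blocks; cluster each block cheaply with
  GC; cluster only the block-group *representatives* exactly with CCBC;
  pull every member into its representative's component. Only
  representatives ever cross block boundaries.
* **MLC**: iterate MLC1 over an increasing threshold schedule
  t₁ < … < tₙ = t. Coarse levels shrink groups cheaply; the expensive final
  threshold only ever sees small groups (those below the cutoff `s` are
  finalized directly at *t*).
* **rMLC**: MLC that recurses on itself wherever an intermediate set larger
  than `M` would be handed to GC or CCBC, and computes alignment batches
  under a configurable limit, bounding peak memory.

Every alignment actually performed is counted by a `comparison_ledger`; the
**f-value** (comparisons divided by N(N−1)/2) makes the saving exact and
auditable, with cached pairs never double-counted. Quality against a
reference partition is the standard clustering **F-measure**: for each
reference class take the best harmonic mean of precision and recall over
predicted clusters, then average weighted by class size. It is 1 exactly
when the reference is reproduced up to labels.

## Similarity: what the thresholds mean

Percent identity is computed from an optimal pairwise alignment
(`Biostrings::pairwiseAlignment`) as identical, unambiguous columns divided
by all alignment columns, gap columns included. Defaults: DNA match +1,
mismatch −2, gap open 5 / extend 2; protein BLOSUM62, gap 11/1. Ambiguity
codes (N, X, …) never count as identities — conservative and deterministic.
All scoring is configurable, and a user-supplied similarity function can
replace the aligner entirely (the clustering layer only consumes a symmetric
pairwise measure in [0, 1]); absolute thresholds are therefore meaningful
only relative to a fixed parameter set.

**Why global alignment is the default.** With local (Smith–Waterman)
scoring, identity is measured on the clipped optimal region. For divergent
pairs (below the scoring scheme's break-even identity, 2/3 under +1/−2) the
optimal local alignment collapses to a short near-perfect window, so
unrelated sequences routinely show clipped identities approaching 1. A
single such spurious edge merges two components under CCBC's transitive
closure. Measured on generated families (within-family identity 0.99,
between-family 0.70, length 150), between-family *local* identities reached
0.95 while *global* identities stayed near 0.72 with a thin tail. Global
identity is monotone in whole-sequence homology, which is what a clustering
threshold is meant to express, so `scope = "global"` is the default;
`scope = "local"` remains available for BLAST-like measurements on curated,
high-identity data.

## Representatives

A group's ideal stand-in is its *central* sequence — the member maximizing
summed similarity to the rest — but finding it costs a within-group half
matrix. The *almost-central* heuristic ranks members by similarity to the
group's greedy representative, samples `k` members at evenly spaced ranks
(rank 1, the representative itself, always included; default `k = 10`), and
returns the exact centre of the sample: O(n + k²) comparisons instead of
O(n²). For groups of at most `k` members it is exact. The even spacing
matters: it covers the group's similarity range instead of only the
representative's neighbourhood. Merged Step-3 clusters recompute their
representative almost-centrally over all members, or over the constituent
group representatives once the union exceeds 10·k members (keeping the cost
O(k²) regardless of cluster size).

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `t` | — | target identity threshold (e.g. ≈ 0.95–0.99 for species-level ITS work; dataset- and scoring-dependent) |
| `block_size` / `block_fraction` | N/10 | MLC1 block size; 0 disables blocking, reducing MLC1 to CCBC (f = 1) |
| `k` | 10 | almost-central subsample; k² must be negligible |
| `s` | 300 | MLC finalization cutoff: groups below `s` go straight to the final threshold |
| `M` | 1000 | rMLC recursion cutoff for intermediate sets |
| `batch_limit` | 10⁶ | maximum uncached alignments per batch; bounds memory, never changes results |

The threshold schedule for MLC/rMLC defaults to gap-halving from the start
threshold (tᵢ₊₁ = tᵢ + (t − tᵢ)/2, stop when the gap is < 0.005, then append
*t*); any strictly increasing explicit schedule is accepted. The halving
rule honours the principle of refining "slightly" at each level while
keeping schedules short (≈ 6 levels from 0.80 to 0.95); accuracy is
insensitive to the exact rule because every level's clustering is exact on
its groups — the schedule only shifts where work happens.

## Numerical and tie-breaking choices

* Sorting ties (equal lengths, equal similarity sums, equal rank
  similarities) always break by ascending sequence id; clusters are numbered
  by first member appearance. Fixed input + config ⇒ byte-identical output.
* Among co-optimal alignments the aligner's deterministic traceback is
  accepted; identity may differ between co-optimal alignments, which is one
  more reason thresholds are scoring-scheme-relative.
* A zero-width local alignment (no positive-scoring pair) has identity 0.
* The pair cache keys on unordered id pairs; a pair is aligned at most once
  per ledger lifetime, and the ledger counts alignments actually performed —
  including those of pre-clustering when it shares the ledger, so reported
  f-values include pre-ordering cost.
* The greedy scan evaluates representatives in small vectorized chunks
  (24 at a time) for speed; membership is still strictly first-match, and
  the few extra alignments a chunk may compute past the first match are
  honestly counted by the ledger (the O(N·m) bound is unaffected).
* MLC hands a group to the next level with its representative first — the
  greedy seed — followed by the remaining members.
* rMLC re-derives recursive schedules by the gap-halving rule from the
  current level's threshold. If a Step-2 representative set fails to shrink
  (no compression, e.g. all singletons), plain CCBC is used instead of
  recursing, guaranteeing termination.

## The synthetic test bed

`generate_families()` plants a known partition: one random root, per-family
ancestors mutated to (1 + between)/2 identity to the root (so ancestor pairs
sit near the between-family target), members point-mutated to the
within-family identity (exact substitution counts at distinct positions;
optional ≤ 2% single-residue indels, off by default). Defaults — DNA,
length 150, within 0.99, between 0.70 — give member pairs ≈ 0.98 and
between-family pairs ≈ 0.72 under the default aligner, so any threshold
strictly between the two levels must yield the planted families, and every
algorithm in the package can be validated against an answer known by
construction.

What the generator does *not* emulate — and what passing its tests therefore
does not demonstrate: real marker data has unequal family sizes spanning
orders of magnitude, gradual similarity continua (near-threshold edges,
where GC's greedy decisions and MLC's level boundaries actually lose
accuracy relative to CCBC), chimeras, alignment-length heterogeneity, and
heavy indel structure.

The two-scale similarity structure also has a cost consequence worth
understanding. MLC's saving over a single MLC1 pass comes from groups
shrinking below the cutoff `s` over several levels *before* the expensive
final threshold, which only happens when similarities form a continuum. On
planted data with exactly two similarity scales, any level threshold
between the scales reproduces the full MLC1 structure at that level, and
the per-group finalization then adds comparisons — so MLC runs slightly
*above* MLC1's cost (e.g. 3,255 vs 2,616 alignments on 500 sequences in 25
families, both ~40× below the 124,750 of the full matrix). On real,
continuum-structured databases the multi-level schedule is what makes the
large-scale runs feasible; on idealized planted data it can only match
MLC1, not beat it. Recovery of well-separated planted families shows
correctness of the algorithms' mechanics, not field accuracy on hard
datasets; on real data the threshold must be tuned with
`optimal_threshold_scan()` against curated references, and the optimum is
specific to the scoring parameters and (for MLC1/MLC) to block size,
schedule and input ordering.

Test and example problem sizes in this package (hundreds of sequences,
length 60–300) are chosen so full-matrix baselines — the yardstick every
f-value and oracle comparison needs — stay cheap; the algorithms themselves
are insensitive to scale beyond the cost model that `M`, `s` and
`batch_limit` control.

## Known limitations

* Identity thresholds are not portable across scoring schemes; published
  cutoffs assume the aligner they were tuned with.
* GC's accuracy depends on input order; only the length-sorted, GC-preorder
  and name orderings of the original protocols are provided.
* The F-measure needs a reference partition covering the evaluated ids;
  partial references are not yet supported.
* No parallel execution; the block structure of MLC1/rMLC is
  embarrassingly parallel in principle but runs sequentially here.

## A worked example

```{r example, eval = FALSE}
sim <- generate_families(family_spec(10, 20, seed = 1))
led <- comparison_ledger()
part <- mlc(sim$sequences, threshold_schedule(0.80, 0.95),
            mlc_config(s = 50), ledger = led)
n_clusters(part)                      # 10
f_measure(part, sim$truth)            # 1
f_value(led, length(sim$sequences))   # << 1
```
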