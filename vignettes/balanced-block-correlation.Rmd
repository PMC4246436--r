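---
title: "Balanced block scheduling for pairwise correlation matrices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Balanced block scheduling for pairwise correlation matrices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(blockcor)
```

## The computation and its structure

Subject stratification from expression data needs the full symmetric
matrix of pairwise coefficients between n subject vectors of p probeset
intensities. blockcor organises that computation around contiguous
*blocks* of subject rows: with k blocks, the work is the set of
k(k+1)/2 unordered block pairs (i, j), i ≤ j, each producing an
m_i × m_j coefficient *tile*; the diagonal tasks (i, i) produce the
symmetric within-block tiles. Assembly places tile (i, j) at the row
range of block i by the column range of block j and mirrors it, so the
output is symmetric to the last bit by construction — the mirrored half is
copied, never recomputed.

The interesting question is scheduling. Shipping every block to every
worker (the `full` strategy) costs k² tiles — each off-diagonal
coefficient twice. Skipping the redundant ordered pairs (`skip`) halves
the arithmetic but concentrates it: worker j holds j + 1 tasks, so loads
run 1…k and the last worker sets the wall time. The `balanced` strategy
keeps the redundancy-free pair set and flattens the loads. Writing
a = (k+1)/2 for the average load, c = ⌈a⌉ and f = ⌊a⌋, worker r takes the
pairs {r, (r+d) mod k} for offsets d = 0…f−1. For odd k every circular
distance 0…(k−1)/2 is generated exactly once this way and all k loads
equal (k+1)/2. For even k the wrap distance d = k/2 pairs worker r with
worker r + k/2 twice over the full circle, so only workers r < k/2 take
that offset; they carry c tasks, the others f. The package states this
guarantee as a law and the test suite verifies it exhaustively for
k = 1…64: exact-once coverage, per-worker loads in {f, c}, and total work
k(k+1)/2.

Two further modes complete the execution model. `serial` runs the pair
list on one worker and is the oracle every other mode is compared against.
`combiner` decouples workers from blocks: the lexicographic pair list is
chunked contiguously into w near-equal slices (spread ≤ 1), and each
worker reads both blocks of its pairs directly from the block store —
computation happens entirely on the map side, so no shuffle step has to
route k(k+1)/2 keyed results onto a mismatched worker count. Contiguous
chunking rather than hashing is deliberate: hash partitioning is exactly
the mechanism that produces skewed worker loads when the key count and
worker count disagree.

The worker contract is share-nothing: a worker sees the block store and
returns finished tiles. `run_job(parallel = TRUE)` satisfies it with a
forked process pool (`parallel::mclapply`) on unix; the default in-process
execution satisfies it trivially. Because every strategy computes each
tile with the same kernel call on the same block bytes, matrices agree
bitwise across strategies and worker counts — the equivalence tests use
`identical()`, not a tolerance.

## Coefficient kernels

Four metrics are supported: `euclidean`, `pearson`, `spearman`,
`kendall`. The scalar kernels define the semantics; the tile kernels
vectorise them.

* Euclidean: √Σ(xⱼ−yⱼ)². Tiles via ‖x‖² + ‖y‖² − 2⟨x, y⟩ with a dense
  cross-product; the subtraction is clamped at zero before the square root
  so near-duplicate subjects cannot produce NaN from a −10⁻¹⁶.
* Pearson: centred cross-product over centred norms, two-pass. Tiles
  precompute per-subject means and norms once per block, not per pair.
* Spearman: Pearson on midranks. Midranks give tied values the mean of the
  positions they span, so ranks always sum to p(p+1)/2 and a perfect
  monotone relationship scores exactly ±1.
* Kendall: τ_b = (C − D)/√((n₀−n₁)(n₀−n₂)), with n₀ = p(p−1)/2 and n₁, n₂
  the tied-pair counts within x- and y-tie groups. After sorting by
  (x, y), D is the inversion count of the y sequence, obtained by
  divide-and-conquer merge counting in O(p log p); the cross-count at each
  merge is vectorised with `findInterval`. τ_b rather than τ_a is the tie
  convention matching the reference statistical environment this package
  cross-checks against; the package also exports `kendall_bruteforce()`,
  the O(p²) enumeration oracle, and the suite requires exact agreement on
  hundreds of tie-rich fixtures.

Degenerate inputs follow one rule: a constant (zero-variance) vector makes
a correlation undefined, so the coefficient is NaN and a warning is
logged; the job keeps running. Missing values parse as NaN at load time
and propagate into every coefficient that touches them; `strict = TRUE`
rejects them at load instead. The clustering step refuses matrices
containing NaN, since a silent imputation there would change the
stratification.

Tile-internal summation order is fixed (ascending probeset index within
each kernel), which is what makes cross-strategy bitwise equality a
testable property rather than an aspiration.

## The block store

`split_blocks()` writes contiguous row slices — sizes ⌈n/k⌉ for the first
n mod k blocks, ⌊n/k⌋ for the rest, so sizes differ by at most 1 — as
delimited text files plus a JSON manifest (k, n, boundaries, per-block row
counts and value checksums). `read_block()` verifies a block against the
manifest before returning it, and the job aborts naming the offending pair
task if a worker hits a corrupted block. The store is a plain directory:
it plays the role a distributed file system plays at cluster scale,
without importing one. Writes go through a shortest-round-trip double
formatter, so a written matrix reads back bitwise identical; the test
suite asserts the round trip with `identical()`.

Subjects-as-rows is the canonical orientation (subjects are what get
correlated and clustered); `read_expression(orientation = "subjects-cols")`
transposes the common series-matrix layout on the way in. Block ids, pair
indices and row ranges are 0-based half-open internally — circular modular
arithmetic is only consistent that way.

## Clustering

`to_distance()` maps correlation matrices through d = 1 − r (range
[0, 2]), the simplest monotone-decreasing transform; Euclidean matrices
pass through unchanged. `hier_cluster()` delegates the agglomeration to
`stats::hclust()` — complete linkage by default, matching that function's
own default, with average and single linkage available because the right
linkage is a study-level choice, not a package-level one. The tests pin
the delegation to an exhaustive-recomputation oracle that rescans all
cluster pairs from the original distance matrix at every merge.
`cut_tree()` undoes the top g − 1 merges; `write_newick()` exports the
tree for tree-viewing tools.

## The synthetic generator

`simulate_expression()` plants g clusters among n subjects assigned
round-robin. Each cluster has a mean vector whose entries are drawn
independently per probeset from N(0, separation²); each cell adds
N(0, noise_sd²) noise; an optional `tie_fraction` of cells is rounded to
the unit grid to create the tied values the rank metrics must handle. The
per-probeset cluster means matter: shifting all probesets by a common
offset would leave rank metrics nearly blind to the structure, whereas
independent draws stress Spearman and Kendall as much as Euclidean
distance.

Defaults are the desk-scale study condition used throughout the suite:
n = 60, p = 500, g = 3, separation = 3, noise_sd = 1 (intensity units).
At those values the expected squared between-cluster distance,
2·separation²·p = 9000, is nine times the within-cluster expectation 2·p,
a clearly separated regime in which exact recovery of the planted labels
is the correct outcome and any failure is a defect, not noise. Setting
separation = 0 removes the structure entirely (the suite checks the
between/within distance ratio collapses to ≈ 1). Generation is
deterministic per seed — Mersenne-Twister with inversion normals, seeded
locally and restored afterwards — so every fixture is reproducible from an
integer.

What the generator does **not** emulate: per-probe affinity differences,
batch effects, heavy-tailed intensity distributions, normalisation
artifacts, or missingness patterns of real array data. Passing tests
therefore demonstrate the scheduling, kernels, assembly and clustering are
correct on well-behaved input; they do not validate biological
preprocessing choices upstream of this package.

## Problem sizes and scale

The equivalence suite runs all four metrics across all strategies at
n = 40, p = 200, k = 8, where even the O(p log p) Kendall kernel over 820
subject pairs per run is quick. One scale test exercises the
paper-shaped input — 559 subjects × 54 675 probesets, Euclidean, balanced
schedule over k = 4 blocks with a forked pool — and verifies a 20-subject
submatrix against a serial reference; it is a completion-and-correctness
check, deliberately free of timing assertions, since wall-clock behaviour
is hardware-bound. Larger runs scale linearly in tiles: balanced work is
k(k+1)/2 tiles of roughly (n/k)²·p flops each.

## Known limitations

* Kendall tiles loop over subject pairs in R; at hundreds of subjects with
  p in the tens of thousands this is the slowest path by far (as the
  metric is intrinsically), and a compiled kernel would be the next step.
* The combiner mode reads blocks per worker with memoisation but no
  cross-worker cache; at very large k the same block may be read by
  several workers.
* Worker failure aborts the job with the offending pair named; there is no
  retry or partial-result recovery.
* `full` strategy exists for work-accounting comparisons; its redundant
  ordered tiles are reconciled (the i ≤ j copy is kept) before assembly
  rather than being averaged.
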