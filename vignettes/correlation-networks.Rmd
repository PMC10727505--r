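---
title: "Constructing large correlation networks with topcorr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constructing large correlation networks with topcorr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(topcorr)
```

## The problem

Correlation analysis is usually the first systematic look at a
high-dimensional biological dataset: which genes, metabolites, CpG sites
or individual cells move together? The obstacle is scale. With n
features there are n(n − 1)/2 unordered pairs, and a dense 64-bit
correlation matrix occupies 64 n²/(8 × 10⁹) GB — past n ≈ 32,000 it no
longer fits in 8 GB of RAM, while typical multiomics feature counts run
far higher. Yet analyses rarely need *all* pairs: they need the
strongest k correlations, the pairs past a threshold, or the pairs whose
correlation *changes* most between two conditions. `topcorr` computes
exactly those quantities with memory proportional to the answer.

## Model and identities

### Correlation projection

For a feature's sample vector x of length m, define
x̂ = (x − μₓ)/‖x − μₓ‖. Then

* ⟨x̂, ŷ⟩ = cor(x, y) (Pearson), and
* d(x̂, ŷ) = √(2(1 − cor(x, y))), an order-reversing bijection between
  correlations in [−1, 1] and distances in [0, 2].

Spearman correlations are Pearson correlations of within-feature ranks
(average ranks at ties, the standard convention), so `method =
"spearman"` simply ranks each column first. The Phi coefficient for
binary variables is Pearson applied to 0/1 columns; columns must already
be 0/1-encoded — no automatic factor coding, which would silently depend
on label order.

The assumptions are the usual ones for these coefficients: Pearson
measures linear association and is sensitive to outliers and heavy
tails; Spearman trades power for robustness; none of them addresses
confounding or causation.

### The joint ± index

Because cor(−x, y) = −cor(x, y) exactly, indexing the 2n points
{x̂ᵢ} ∪ {−x̂ᵢ} in one exact ball tree lets a single k-nearest-neighbor
query retrieve the strongest correlations *of either sign*: a match on a
negated point at distance d means a correlation of −(1 − d²/2). The tree
is exact (triangle-inequality pruning only), and ties in distance break
by point index, so every query result is deterministic and identical to
a brute-force scan.

### Global top-k approximation

A k-NN index answers "the top correlations *of this feature*", not "the
global top-k". `topcorr` queries every feature for its
k′ = ⌈a·k/n⌉ nearest candidates (capped at 2n) and merges: concatenate,
canonicalize each pair to i < j, drop duplicates, partition to the top k
by the ranking key, sort. The approximation factor a ≥ 1 is the only
approximation in the pipeline:

* a large enough that k′ ≥ 2n ⇒ exhaustive, provably identical to the
  full-matrix backend (`topk_from_matrix()`), which the test suite
  asserts on hundreds of random instances;
* smaller a trades sensitivity for speed. The default a = 10 is
  deliberately conservative. The source literature's closed-form mapping
  from desired sensitivity to a is typographically ambiguous in print,
  so this package does not implement a guessed formula;
  `empirical_sensitivity()` measures the relationship on data instead
  (it is provably non-decreasing in a, and the tests assert it).

Threshold queries need no approximation at all: all pairs with |r| ≥ t
lie within radius √(2(1 − t)) of some query, and radius queries are
exact. `threshold_correlation_search()` therefore always equals
`threshold_from_matrix()`.

### Differential space

For two conditions with m₁ and m₂ samples, the paired representations

δ(x) = (x̂₁, x̂₂) and κ(y) = (ŷ₁, −ŷ₂), both of norm √2,

satisfy ⟨δ(x), κ(y)⟩ = cor(x₁, y₁) − cor(x₂, y₂) ∈ [−2, 2], with the
distance law g = 2 − d²/2, d ∈ [0, 2√2]. Building the joint tree over
±δ and querying with κ finds the largest correlation *changes* with the
identical batching/merging contract. Conditions may have different
sample counts. An optional bootstrap wrapper
(`differential_bootstrap()`, off by default) reports per-edge selection
frequencies over resamples; the reference analysis names such a strategy
without parameters, so b is user-chosen.

## Determinism and numerical choices

* Ordering is fully specified everywhere: descending ranking key
  (|value| by default, signed optionally), ties by ascending (i, j).
  Results are invariant to batch size and worker count, asserted
  byte-for-byte on written files.
* Correlations are clipped to [−1, 1] (differences to [−2, 2]) to absorb
  floating-point rounding; projections must satisfy unit norm and zero
  mean within 1e-10.
* The two backends compute values along different floating-point routes
  (BLAS crossproduct vs 1 − d²/2), so cross-backend agreement is to
  1e-10, not bitwise; within a backend, outputs are bitwise stable.
* Constant features have no defined correlation and error out at
  projection time with the offending feature named;
  `preprocess_features()` (clamp negatives to 0 → drop constants → drop
  exact duplicates, in that fixed order, since clamping can create both)
  is the sanctioned way to clean a matrix first.
* Each query requests two extra neighbors beyond k′ so its own ±
  points (always present at distances 0 and 2) never consume the
  candidate budget, then self-matches are dropped by feature id.
* The `dual_tree` flag in `search_config()` is accepted as a performance
  hint; the current implementation uses the same exact single-tree
  search path either way, so results are identical by construction.
* Missing values are rejected at validation (no pairwise-complete
  handling); memory-guarded helpers (`correlation_distance_matrix()`)
  refuse to allocate beyond a configurable GB cap using the
  64 n²/(8 × 10⁹) formula (decimal GB on purpose).

## Statistics

P-values use t = r√(m − 2)/√(1 − r²) with m − 2 degrees of freedom
(two-sided); |r| = 1 maps to p = 0. Bonferroni multiplies by
(n² − n)/2. For FDR control on a top-k list the full p-value
distribution is unavailable by design, so `bh_truncated_adjust()`
computes the Benjamini–Hochberg step-up values *as if* all unseen
p-values were 1, without materializing them:
P̂(i) = min(min_{i≤j≤k} m·Pⱼ/j, 1). This is exact BH when k = m and a
conservative upper bound otherwise (both properties are tested against a
reference implementation). A stricter tie-replacement using
u = m/(k + 1) appears in the source literature with ambiguous intent; it
is available behind `u_replacement = TRUE` and off by default.

## What the synthetic generators emulate — and what they don't

`generate_block_correlated()` uses a latent-factor construction: block
members are s·z + noise_sd·ε with shared z, giving expected within-block
correlation v/(v + noise_sd²) with v = s²; s is solved from the
requested rho. Defaults rho = 0.9, noise_sd = 0.3 represent the "strong
planted signal amid independent noise" regime the search backends are
meant to separate. `generate_two_condition()` plants per-pair
correlations via x_j = ρx_i + √(1 − ρ²)ε. `generate_celllike()` draws
group centroids with spread `group_effect` and unit within-group noise,
emulating the shape (20 cell types × 10⁴ cells × 10 functional markers)
of a mass-cytometry benchmark.

These generators produce Gaussian, marginally well-behaved data. They do
not emulate counts, zero inflation, compositionality, batch effects or
heavy tails — so a green test establishes the *algorithmic* contracts
(recovery, exactness, determinism), not robustness to real omics
artifacts. Spearman mode exists precisely because real data violate
Gaussianity.

## The single-cell coordination recipe

Cells are grouped into types; the question is which *pairs of types*
share top-ranked functional similarity, and how that changes between two
timepoints. Per replicate: (1) `dual_bootstrap_sample()` draws n_g cells
with replacement from each type, then the target count from that
intermediate sample — equalizing type sizes while preserving
within-type variation; (2) `count_topk_group_pairs()` treats cells as
the features being correlated (markers are the samples), takes the top
fraction (reference setting: top-0.01% Spearman) of cell-cell pairs, and
tallies them into unordered type pairs — counts sum to k by
construction; (3) `effect_size_screen()` computes Cliff's δ of the
condition-2 versus condition-1 counts across replicates and keeps
|δ| > 0.622, the conventional "very large" effect threshold, labelling
increase/decrease. The reference analysis resamples 1,000 times; tests
use 50–100 replicates at desk scale. Self-pairs are always excluded;
within-type pairs are counted.

## Known limitations

* Negatively correlated features map to *large* embedding distances by
  design; visualizing them as neighbors is unsupported.
* The ball tree's advantage erodes as the sample count m grows (the
  curse of dimensionality in query time); for large m a batched
  matrix-product backend becomes competitive — out of scope here beyond
  the exact matrix backend.
* Top-k output is asymmetric by default (each unordered pair appears
  once, i < j); `symmetrize()` or `--symmetrize` emits both
  orientations.
* No missing-value support, no partial correlations, no Kendall's τ,
  no coefficients without a Pearson reduction.

## A compact demonstration

```{r demo}
sim <- generate_block_correlated(60, 40, block_sizes = c(5, 5),
                                 rho = 0.9, noise_sd = 0.3, seed = 7)
top <- topk_correlation_search(sim$matrix, k = 20,
                               search_config(approximation_factor = 20))
head(as.data.frame(top), 5)
empirical_sensitivity(sim$matrix, k = 20, a_grid = c(1, 5, 20, 360))
```

Everything shown above is recomputed by the package at render time; no
empirical claim in this vignette is made that the test suite does not
itself compute.
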