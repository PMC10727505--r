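# topcorr

Large-scale correlation network construction for high-dimensional
biological data — full matrices, approximate global top-k networks,
thresholded networks, and differential (two-condition) networks — without
ever materializing the n × n correlation matrix when you don't want to.

## Who this is for

Modern omics and single-cell studies routinely measure tens of thousands
to hundreds of thousands of features (genes, CpG sites, metabolites,
individual cells) on comparatively few samples. A first-pass analysis is
almost always correlational, but already at n = 1,000 features there are
n(n − 1)/2 = 499,500 pairs to examine, and a dense double-precision
correlation matrix needs 64 n² / (8 × 10⁹) GB — more than 8 GB at
n = 32,000 and more than 32 GB at n = 64,000. `topcorr` targets exactly
this regime: it finds the strongest k correlations (or all correlations
past a threshold, or the strongest correlation *changes* between two
conditions) with memory proportional to the output, not to n².

## The method

Every feature vector x is **correlation-projected** onto a mean-centered
unit vector

    x̂ = (x − μₓ) / ‖x − μₓ‖,

so that the scalar product of two projections equals their Pearson
correlation, ⟨x̂, ŷ⟩ = cor(x, y), and Euclidean distance is
order-equivalent to correlation:

    cor(x, y) = 1 − d(x̂, ŷ)² / 2.

Three consequences drive the package:

1. **Full matrices** are one BLAS crossproduct X̂ᵀX̂
   (`full_correlation_matrix()`); Spearman comes free by ranking columns
   first, the Phi coefficient by feeding 0/1 columns.
2. **Top-k / threshold search** becomes a nearest-neighbor problem. A
   single exact **ball tree is built jointly over {x̂, −x̂}** (since
   cor(−x, y) = −cor(x, y), a near neighbor among negated points is a
   strong *negative* correlation). Each feature queries its
   k′ = ⌈a·k/n⌉ nearest candidates — `a` is the *approximation factor* —
   and batches are merged, deduplicated and partitioned into the global
   top-k. With k′ ≥ 2n the result is provably exact; threshold (radius)
   queries at r = √(2(1 − t)) are *always* exact. Peak extra memory is
   O(n·k′ + k) edge records.
3. **Differential networks**: features in two conditions are paired into
   differential-space vectors δ(x) = (x̂₁, x̂₂) and κ(y) = (ŷ₁, −ŷ₂) with
   ⟨δ(x), κ(y)⟩ = cor(x₁, y₁) − cor(x₂, y₂), so the same joint-index
   machinery finds the largest correlation *changes*
   (`topk_differential_search()`), with g = 2 − d²/2.

Supporting machinery: t-statistic p-values (t = r√(m−2)/√(1−r²)),
Bonferroni and a *truncated* Benjamini–Hochberg adjustment that treats
unseen p-values as 1 (an upper bound computed without instantiating all
(n² − n)/2 of them), correlation-preserving embedding coordinates for
t-SNE/UMAP/MDS, seeded synthetic generators with planted ground truth,
and a single-cell coordination recipe (dual bootstrap → top-k cell-pair
counting per cell-type pair → Cliff's δ screening at the "very large"
threshold 0.622).

Note: the closed-form mapping from a desired sensitivity to an
approximation factor is not implemented (the printed formulas in the
source text are ambiguous); measure it empirically with
`empirical_sensitivity()` instead.

## Worked example

```r
library(topcorr)

sim <- generate_block_correlated(n_features = 200, m_samples = 50,
                                 block_sizes = c(6, 6), rho = 0.9,
                                 noise_sd = 0.3, seed = 42)
top <- topk_correlation_search(sim$matrix, k = 30,
                               search_config(approximation_factor = 50))
top
#> <edge_list> 30 edges (correlation, ranking = abs)
#>    feature_i feature_j     value i  j
#> 1         f1        f3 0.9221470 1  3
#> 2         f7       f12 0.9212469 7 12
#> 3         f9       f12 0.9206915 9 12
#> ...

length(intersect(paste(top$i, top$j), paste(sim$truth$i, sim$truth$j)))
#> [1] 30        # all 30 planted within-block pairs recovered

head(as.data.frame(add_edge_pvalues(top, m = 50, n_features = 200,
                                    adjust = "bh")), 3)
#>   feature_i feature_j     value i  j            p        p_adj
#> 1        f1        f3 0.9221470 1  3 1.968913e-21 1.569585e-17
#> 2        f7       f12 0.9212469 7 12 2.567802e-21 1.569585e-17
#> 3        f9       f12 0.9206915 9 12 3.020357e-21 1.569585e-17

empirical_sensitivity(sim$matrix, k = 30, a_grid = c(1, 10, 50, 2700))
#>      a kprime sensitivity
#> 1    1      1   0.3333333
#> 2   10      2   0.5666667
#> 3   50      8   1.0000000
#> 4 2700    400   1.0000000

estimate_full_matrix_memory_gb(32000)
#> [1] 8.192
```

The two planted 6-feature blocks contribute 2 × 15 = 30 within-block
pairs at r ≈ 0.9; the index backend recovers all of them at a = 50,
and the sensitivity table shows the exactness guarantee
kicking in once k′ reaches 2n = 400. The BH-adjusted p-values are upper
bounds computed as if the 19,870 unreported pairs all had p = 1.

## Command line

```sh
Rscript -e 'topcorr::topcorr_cli()' simulate --output sim.tsv \
    --n-features 200 --m-samples 50 --block-sizes 6,6 --seed 42
Rscript -e 'topcorr::topcorr_cli()' topk --input sim.tsv --k 0.1% \
    --approximation-factor 10 --output edges.tsv
```

Subcommands: `matrix`, `topk`, `threshold`, `diff-topk`, `embed-coords`,
`pvalues`, `preprocess`, `simulate`, `cell-coord`. `--k` accepts an
absolute count, a multiple of n (`100n`), or a fraction of all pairs
(`0.1%`). An installed copy of the wrapper script lives at
`system.file("cli", "topcorr", package = "topcorr")`.

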