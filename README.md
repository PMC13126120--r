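# grndiff

Differential analysis of binary gene regulatory networks.

Single-cell GRN-inference pipelines (CellOracle, SCENIC, ...) summarise a
transcription factor's activity as a binary target-by-sample matrix:
entry `(g, i)` is 1 when the TF→target link is active in sample `i`.
`grndiff` answers the question practitioners actually ask of these
matrices — *does this TF's regulatory program differ between two groups
of samples?* — for which classical per-gene differential tests are often
underpowered when the signal is sparse, diffuse, or coordinated across
targets.

## Methods

Five complementary tests share one label-permutation engine
(`p_perm = (1 + #exceedances) / (R + 1)`, ties counted, minimum
`1/(R+1)`):

| method | statistic |
|---|---|
| `global_u` | Hamming-kernel dissimilarity ratio `T_d = U_AB / W`, with `W` the pair-count-weighted pooled within-group mean distance |
| `global_f` | PERMANOVA-style pseudo-F `F* = D_between / D_within` on Jaccard distances |
| `pca` | absolute difference in mean PC1 scores, `S = |z̄_A − z̄_B|` |
| `local_u` | per-feature two-sided Mann–Whitney p-values combined by Fisher's method, `T = −2 Σ ln P_g` |
| `fisher` | exact hypergeometric p-value of the pooled active/inactive 2×2 table, referred to the permutation null |

Distances, per-feature p-value lookups, the hypergeometric support, and
the PCA embedding are computed once per matrix; permutation replicates
only re-partition cached quantities, so 2000 permutations per test are
desk-scale.

The package also ships a five-scenario simulator (`simulate_grn`:
normal, balanced, noisy, coordinated, null signal structures at G = 80
features, N = 40 samples by default), an empirical power benchmark
(`power_study`), and TF-level utilities: top-k effect sizes
(`effect_size_topk`), BH adjustment, differential-activation scores for
preranked enrichment (`differential_activation_scores`), structural
category classification (`classify_tf_matrix`), and a multi-TF driver
(`run_tf_suite`). A thin CLI (`inst/cli/grndiff`) exposes
simulate/test/power/classify/effectsize subcommands.

## Worked example

```r
library(grndiff)

sim <- simulate_grn("normal", gamma = 0.25, seed = 42)
sim
#> Simulated dataset: scenario 'normal', 40 samples x 80 features, 20 signal features (seed 42)

fit <- grn_test(sim, n_perm = 1999, seed = 42)
fit
#> Group-difference tests on a binary regulatory matrix (40 x 80, n_A = 20, n_B = 20)
#>    method  observed n_perm p_perm
#>  global_u 1.118e+00   1999  5e-04
#>  global_f 1.049e+00   1999  5e-04
#>       pca 1.501e+00   1999  5e-04
#>   local_u 3.051e+02   1999  5e-04
#>    fisher 3.859e-10   1999  5e-04
```

With a quarter of the features activated at rate 0.3 in the case group
versus 0.05 in controls (background 0.1 in both), every test rejects at
its smallest attainable permutation p-value, `1/2000 = 5e-04`: the
observed dissimilarity ratio (`T_d = 1.118`), pseudo-F (`1.049`), PC1
separation (`1.501`), combined Mann–Whitney statistic (`305.1`) and
pooled Fisher p-value (`3.9e-10`) are each more extreme than all 1999
relabelings. Downstream summaries agree with the generating structure:

```r
effect_size_topk(sim$matrix, sim$labels)
#> [1] 0.385
classify_tf_matrix(sim$matrix, sim$labels)
#> TF matrix category: Normal
#>   rate_A = 0.161, rate_B = 0.087, asymmetry = 0.073
#>   noise = 0.107, bidirectionality = 0.000, within_corr = 0.017
```

Real data enter through `read_binary_matrix()` (dense TSV/CSV with
targets as rows and samples as columns, or Matrix Market with sidecar id
files) and `read_group_labels()`; see the vignette
(`vignettes/differential-grn-testing.Rmd`) for the statistical details
and design notes.

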