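# wbdeconv

Two-stage *in silico* deconvolution of heterogeneous (whole-blood-like)
gene expression data.

Bulk expression measured in a mixed tissue confounds two biologically
distinct signals: changes in **cell-type composition** and changes in
**cell-type-specific expression**. `wbdeconv` implements the two-stage
strategy used to disentangle them in peripheral whole blood, where the
mixture is well described by the linear model

```
x_ij = sum_k  w_ik * h_kj + e_ij
```

with `x_ij` the observed expression of gene *j* in sample *i*, `w_ik` the
proportion of cell type *k* in sample *i* (rows of `W` on the probability
simplex), and `h_kj` the expression of gene *j* in cell type *k*.

**Stage 1 — reverse deconvolution.** A basis (signature) matrix `H` of
marker-gene expression is built from isolated leukocyte profiles:
fold-change prefiltering across all pairwise cell-type contrasts, then a
multinomial elastic-net selection path (`glmnet`, lambda by the 1-SE rule)
scored by how well the resulting basis predicts measured leukocyte
differentials; the sparsest basis achieving minimal lymphocyte RMSE wins.
Per-sample composition is then estimated by least squares constrained to
the simplex (`w >= 0`, `sum(w) = 1`), solved by quadratic programming with
an explicit KKT verification.

**Stage 2 — forward deconvolution (csSAM-style).** With composition in
hand, group-wise regression of each gene on `W` (no intercept, linear
scale) estimates cell-type-specific expression per group; the
case-minus-control contrast is tested with one-tailed up/down permutation
FDR curves (group labels shuffled, composition kept attached to samples),
with calls made at the customary permissive FDR of 30%.

Downstream helpers cover the signal-to-noise ranking statistic
`d_kj = (h1_kj - h2_kj) / sqrt(se1^2 + se2^2)` with `.rnk` export,
hypergeometric tissue-set enrichment with Benjamini-Hochberg correction,
and a lymphocyte up/down **ratio score** (mean expression of up-regulated
signature genes divided by mean expression of down-regulated ones) that
survives convolution and transfers across platforms. A synthetic-data
module generates reference panels, Dirichlet-composed mixtures with
group-wise composition shifts and cell-type-specific fold-change spikes,
and noisy leukocyte differentials, so every stage can be benchmarked
against known ground truth.

Intended users: computational biologists analysing blood (or other
mixed-tissue) expression studies who need composition estimates,
cell-type-resolved differential expression, or both, without
time-matched flow cytometry.

## Worked example

```r
library(wbdeconv)

# reference panel of 7 isolated leukocyte populations, 1000 genes
sim <- simulate_panel(K = 7, p = 1000, markers_per_type = 20,
                      replicates = 5, seed = 42)
profiles <- 2^sim$truth$profiles_log2

# 24 cases vs 24 controls; CD4+ T and NK genes up-regulated in cases
mx <- simulate_mixtures(
  profiles, n_per_group = 24,
  de_spec = data.frame(cell_type = c("CD4T", "NK"), n_genes = 50,
                       fold = 3, direction = "up"),
  noise_cv = 0.02, seed = 43
)

# stage 1: infer composition from the mixtures with a marker basis
basis <- basis_matrix(profiles[unlist(sim$truth$markers), ],
                      scale = "linear")
comp <- deconvolve(mx$expr, basis)
comp
#> <deconv_result> 48 samples (48 solved)
head(tidy(comp), 3)
#> # A tibble: 3 × 5
#>   sample_id cell_type  proportion residual_norm status
#>   <chr>     <chr>           <dbl>         <dbl> <chr>
#> 1 s001      neutrophil     0.469           147. ok
#> 2 s001      eosinophil     0.239           147. ok
#> 3 s001      monocyte       0.0730          147. ok
round(aggregate_lymphocyte(comp)[1:4], 3)
#>  s001  s002  s003  s004
#> 0.219 0.298 0.195 0.190

# stage 2: cell-type-specific differential expression (cases = "g2")
fdr <- permutation_fdr(mx$expr, comp$composition, mx$design,
                       n_perm = 200, case = "g2", seed = 44)
fdr
#> <cs_fdr> 200 random permutations; 75 calls at FDR <= 0.30
#> # A tibble: 3 × 3
#>   cell_type direction     n
#>   <chr>     <chr>     <int>
#> 1 CD4T      down         10
#> 2 CD4T      up           64
#> 3 NK        up            1
```

Every solver status is `"ok"`: all 48 samples were assigned a composition
on the simplex (the `residual_norm` column is the per-sample fit residual
`||Hw - x||`). The estimated lymphocyte fractions (B + CD4+ T + CD8+ T +
NK) sit in the 0.19–0.30 range typical of blood. At FDR <= 0.30 the
cell-type-specific analysis calls 64 genes up-regulated in CD4+ T cells in
the case group — dominated by the planted spike-ins — plus a single NK
call and a handful of CD4+ T down-calls near the permissive threshold.
`autoplot(fdr)` draws the calls-vs-FDR curves per cell type;
`ranking_statistic(fdr$fit)` and `export_rnk()` produce ranked lists for
pre-ranked gene-set enrichment tools, and `build_ratio_signature()` +
`ratio_score()` turn the calls into a per-sample up/down ratio.

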