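# cellhazard

Single-cell omics shows how heterogeneous tumours and tissues are, but
cohorts linking single-cell data to survival outcomes are rare, while bulk
RNA-seq with clinical follow-up is abundant. **cellhazard** connects the two:
it deconvolves bulk (and spatial) transcriptomes to *single-cell* resolution
against an annotated single-cell reference and estimates how much each
individual reference cell contributes to patient hazard — so prognostic
signal can be attributed to specific cell states rather than whole cell
types. It is aimed at computational biologists analysing tumour or disease
cohorts with a matched single-cell atlas.

## The model

Three stages, fitted sequentially, each frozen before the next:

1. **Latent cell states.** A batch-conditional variational autoencoder with a
   Poisson count likelihood: counts `x_c ~ Poisson(l_c · f(z_c, p_c))`, with
   standard-normal prior on the latent state `z_c`, per-cell mean count
   `l_c`, and batch one-hot `p_c`.
2. **Deconvolution.** Bulk expression is negative binomial,
   `e_bg ~ NB(mu_bg, alpha_g)` with
   `mu_bg = r_g · sum_c f(z_c, p_c)_g · m(z_c)_b + o_g`:
   per-gene capture rate `r_g`, shift `o_g`, and dispersion `alpha_g`, and a
   learned cell-fraction map `m` softmaxed **across cells**, so each sample's
   fractions sum to one. The same model maps spatial spots.
3. **Per-cell hazard contributions.** An extended Cox model
   `h_b(t) = h0(t) · exp(eta_b)` with
   `eta_b = sum_c beta(z_c) · m(z_c)_b`, where `beta(·)` is a network on the
   latent state, fitted by maximising the Breslow or Efron partial
   log-likelihood with early stopping, and evaluated by the test-split
   concordance index and integrated Brier score.

Downstream: within-cluster permutation importance (which clusters' internal
heterogeneity drives prediction), gene–contribution correlation ranking,
spatial hazard maps with quantile clipping for display, and cross-dataset
similarity of gene correlation profiles. A simulation module generates
clustered references, pseudo-bulk mixtures with known cluster proportions,
and Cox-distributed survival times, so every stage is verifiable offline.
See `vignettes/methods.Rmd` for assumptions, defaults, and limitations.

## Worked example

```r
library(cellhazard)

# a 4-cluster reference; half becomes the model's reference, the other half
# builds 150 pseudo-bulk samples with known cluster proportions
sim    <- simulate_reference(n_cells = 300, n_genes = 120, n_clusters = 4,
                             n_batches = 2, seed = 1)
halves <- split_reference(sim$reference, fraction = 0.5, seed = 2)
pb     <- simulate_pseudobulk(halves$bulk_source, n_bulk = 150,
                              cells_per_sample = 500, seed = 3)
surv   <- simulate_survival(pb$true_proportions, c(2, -2, 1, 0),
                            censor_fraction = 0.3, seed = 4)

vae    <- fit_vae(halves$reference, max_epochs = 150, seed = 5)
deconv <- fit_deconvolution(pb$counts, vae, max_epochs = 1500, seed = 6)
hazard <- fit_hazard(deconv, surv, seed = 7)

agg <- aggregate_fractions(deconv)                       # samples x clusters
cor(as.vector(agg), as.vector(pb$true_proportions))      # 0.987
glance(hazard)
#> # A tibble: 1 × 6
#>   ties    cindex_train cindex_val cindex_test ibs_test epochs
#>   <chr>          <dbl>      <dbl>       <dbl>    <dbl>  <int>
#> 1 breslow        0.690      0.655       0.735    0.172     57
```

The estimated cluster-proportion matrix correlates at r = 0.99 with the
generating proportions, and the held-out c-index of 0.735 says that samples
richer in adverse cells are correctly ranked to fail earlier (0.5 would be
chance). Cluster means of the per-cell contributions track the generating
coefficients `(2, -2, 1, 0)` up to the location shift the partial likelihood
cannot identify:

```r
tapply(hazard$beta, deconv$cluster, mean)
#> cluster_1 cluster_2 cluster_3 cluster_4
#>      3.34     -0.67      3.17      0.22
cor(as.numeric(tapply(hazard$beta, deconv$cluster, mean)), c(2, -2, 1, 0))
#> [1] 0.924

permutation_importance(hazard, cell_fractions(deconv), deconv$cluster,
                       surv, n_perm = 20, seed = 8)
#> # A tibble: 4 × 4
#>   cluster   decrement       se n_cells
#>   <chr>         <dbl>    <dbl>   <int>
#> 1 cluster_1 0.0000343 0.000108      34
#> 2 cluster_2 0.00279   0.000273      38
#> 3 cluster_3 0.00634   0.000931      40
#> 4 cluster_4 0.00252   0.000570      38
```

The permutation decrement measures how much *within-cluster* heterogeneity
of contributions matters for ranking samples; here the signal is carried by
cluster composition, so all decrements are small. `autoplot()` methods exist
for fits, permutation reports, and spatial maps; `tidy()`/`glance()` return
tibbles throughout.

A thin CLI wraps the same functions
(`inst/cli/cellhazard.R simulate | fit-vae | deconvolve | fit-hazard |
run-all`), driven by a YAML configuration (`read_pipeline_config()`), with
per-stage checkpoints, a JSON manifest, and hash-verified resumption — see
`?run_pipeline`.

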