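---
title: "Single-cell hazard deconvolution: model, assumptions, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-cell hazard deconvolution: model, assumptions, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

cellhazard estimates how much each cell in a single-cell RNA-seq reference
contributes to patient survival, using bulk RNA-seq cohorts with outcome data.
It does this in three frozen stages: a latent-state model of the reference, a
deconvolution of the bulk cohort at single-cell (not cell-type) resolution,
and an extended Cox proportional-hazards model whose covariates are the
per-cell fractions. This vignette documents the model, its tunable
parameters, the simulation design used for validation, and the numerical
choices that are not forced by the model itself.

## Stage 1: latent cell states

Raw counts $x_c \in \mathbb{N}^G$ for cell $c$ are modelled with a
batch-conditional variational autoencoder. The latent state $z_c \in
\mathbb{R}^M$ has a standard-normal prior; counts are Poisson,

$$x_{cg} \sim \mathrm{Poisson}\!\left(l_c \, f_\theta(z_c, p_c)_g\right),$$

where $l_c$ is the mean count over genes for cell $c$ (so the decoder
$f_\theta$ carries relative, not absolute, expression), and $p_c$ is the
one-hot batch (patient) label concatenated to both the encoder and the
decoder input. The posterior $q(z_c \mid x_c, p_c)$ is a diagonal Gaussian
produced by the encoder; training maximises the evidence lower bound
(Poisson reconstruction log-likelihood minus the closed-form KL divergence
from the prior) with the reparameterisation trick.

Choices and defaults:

- **Latent dimension** `latent_dim = 10`; encoder and decoder are MLPs with
  two hidden ReLU layers of 128 units; the decoder output head is a softplus,
  floored at `rate_floor = 1e-8` so a zero rate can never meet a non-zero
  count.
- **Encoder input** is `log1p` of the counts next to the batch one-hot; the
  likelihood itself is always evaluated on raw counts.
- **Optimisation**: Adam (`lr = 1e-3`), minibatches of 128 cells, at most 400
  epochs. Cells are split 85/10/5 into training/validation/test at random
  (unstratified, seeded). Early stopping monitors a deterministic validation
  objective — the ELBO with the reconstruction term evaluated at the posterior
  mean and the KL term exact — with patience 20 epochs; the best parameters
  are restored and frozen. The held-out test reconstruction log-likelihood
  per cell is reported.
- The networks are implemented in-package as small dense MLPs with analytic
  backpropagation; every gradient in all three stages is closed-form, and all
  stochasticity flows through seeded draws, so fits are exactly reproducible
  given a seed.

## Stage 2: deconvolution at single-cell resolution

Bulk expression $e_b \in \mathbb{R}^G$ is negative binomial,

$$e_{bg} \sim \mathrm{NB}\!\left(\mu_{bg}, \alpha_g\right), \qquad
\mu_{bg} = r_g \sum_{c=1}^{C} f_\theta(z_c, p_c)_g \, m(z_c)_b + o_g,$$

with per-gene capture rate $r_g$, shift $o_g$, and inverse-dispersion
$\alpha_g$, all positive and shared across samples. The cell-fraction map
$m$ is an MLP from the latent state to one logit per sample, softmaxed
*across cells*, so $\sum_c m(z_c)_b = 1$ for every sample after every
optimiser step — the normalisation is structural, not a penalty. Spatial
spots use the identical model with spots in place of samples.

Choices and defaults:

- **NB parameterisation**: mean $\mu$ and inverse-dispersion $\alpha$ with
  variance $\mu + \mu^2/\alpha$ ($\alpha$ is the `size` of `dnbinom`); large
  $\alpha$ recovers the Poisson.
- **Positivity** of $r, o, \alpha$ via softplus of unconstrained parameters;
  $r$ is moment-initialised from the ratio of bulk to decoder gene means.
- **Latent input** is the posterior mean of each cell (deterministic), not a
  fresh posterior sample.
- **Optimisation**: full-batch Adam (`lr = 5e-3`, up to 3000 iterations) with
  a step decay to 1/3 and then 1/10 of the rate over the last half of the
  run, which removes terminal oscillation; optimisation stops early when the
  log-likelihood improves by less than `tol` (relative) per 50 iterations.
  Stage-1 parameters are never touched (the fit records the decoder hash so
  this is checkable).
- **Gene handling**: case-sensitive symbol intersection with the reference;
  dropped genes are counted in a message. Either matrix orientation is
  accepted (detected by gene-name overlap) and non-integer expression is
  rounded with a warning before the count likelihood.

A caveat on per-cell fractions: the likelihood only sees fractions through
the mixture mean, and cells of the same cluster have near-identical decoder
profiles, so reallocating mass *within* a cluster barely changes the
objective. Duplicate samples therefore receive fraction columns that agree
to roughly $10^{-3}$ after cluster aggregation but only to about
$10^{-2}$ cell by cell. Cluster-aggregated fractions are the robust
read-out; per-cell values should be interpreted through their latent-space
neighbourhoods, not individually.

## Stage 3: per-cell hazard contributions

The hazard for sample $b$ is $h_b(t) = h_0(t)\exp(\eta_b)$ with

$$\eta_b = \sum_{c=1}^{C} \beta_{\theta'}(z_c) \, m(z_c)_b,$$

where $\beta_{\theta'}$ is an MLP (two hidden layers of 64 units, linear
scalar output, so contributions are signed) from the latent state. With
fractions frozen, $\beta$ is fit by maximising the Cox partial
log-likelihood; both the Breslow and the Efron tie corrections are
implemented with analytic gradients and log-sum-exp stabilisation. Because
fractions sum to one per sample, adding a constant to every contribution
shifts every $\eta_b$ equally and leaves the partial likelihood unchanged —
contributions are identified up to location (and interpretable through
contrasts), which is why correlation-based evaluation is used.

Choices and defaults:

- **Ties**: `"auto"` uses Efron when tied event times exist in the training
  split and Breslow otherwise; both are selectable.
- **Splits**: bulk samples 60/20/20 into training/validation/test; training
  with zero events is an error. Early stopping on the validation partial
  likelihood, patience 20, Adam `lr = 1e-3`, up to 2000 full-batch epochs.
- **Evaluation**: Harrell's concordance index — comparable pairs are those
  where the shorter time is an event (pairs of events tied in time are
  excluded); ties in the predictor score 1/2. The integrated Brier score
  uses the Breslow baseline cumulative hazard from the training split,
  Kaplan-Meier inverse-probability-of-censoring weights, and a trapezoidal
  integral over 100 evenly spaced points up to the 80th percentile of
  observed time; an IPCW weight of zero at a required time is an error.
- `resample_cindex_ci()` refits only stage 3 under independent splits and
  reports a percentile confidence interval of the test c-index; the
  generalisation criterion is a lower bound above 0.5.

## Downstream analyses

- **Permutation importance** shuffles contributions among the cells of one
  cluster at a time, recomputes $\eta$ and the c-index (on the full cohort by
  default; a sample subset is selectable), and reports the mean decrement
  with its standard error over `n_perm` permutations (default 10). Note that
  the statistic measures *within-cluster heterogeneity* of contributions: a
  cluster whose cells share one value is untouched by permutation and scores
  exactly zero, however large that value is. On a single dataset the baseline
  c-index is itself one draw from the null, so a signal-free cluster's
  decrement is zero only in expectation across datasets.
- **Gene-contribution correlation** ranks genes by the Pearson correlation
  across cells between the decoder's denoised expression (the default; raw
  counts by mask are possible by passing them as the matrix) and the
  contributions, optionally within a caller-supplied cell subset; the top and
  bottom `top_k` (default 30) are marked. Zero-variance genes get $r = 0$
  and a flag.
- **Spatial hazard** scores each spot by
  $\sum_c \beta(z_c)\, m^{\mathrm{spot}}(z_c)_s$. For display, a copy is
  clipped to the 2.5% and 97.5% quantiles (linear-interpolation convention)
  of the raw scores; the raw scores are retained, and clipping against those
  retained raw scores is a projection and therefore idempotent. Group means
  (e.g. over expression-derived spatial clusters, which this package does
  not compute itself) use the raw, unclipped scores.
- **Cross-dataset similarity** is the Pearson correlation of per-gene
  correlation vectors over the shared gene vocabulary (at least 10 genes).

## The simulation design

The synthetic module is the package's benchmark and defines the conditions
under which the method is validated:

- A reference of 500 cells, 200 genes, 5 clusters, and 2 batches. Each
  cluster has a gene-wise log-mean profile drawn around a shared baseline
  (`base_logmean = log 2`, cluster SD 1); batches add gene-wise log-offsets
  (SD 0.2); counts are negative binomial with inverse-dispersion 10. These
  magnitudes give libraries of a few hundred counts and clearly separated but
  overlapping clusters, and keep every mixture mean available in closed form
  for testing.
- The reference is split in half, stratified by cluster; 300 pseudo-bulk
  samples are built from the *other* half by drawing 1000 cells per sample
  with replacement, multinomially across clusters with Dirichlet(1)
  proportions, and summing their counts — so deconvolution never sees the
  cells that produced a sample.
- Survival times come from the constant-baseline Cox model
  $T = -\log(U) / (\lambda_0 e^{\eta})$ with $\eta$ the proportion-weighted
  cluster coefficients. Censoring is independent exponential with its rate
  calibrated by bisection to the requested expected censored fraction
  (default 0.3, a typical cohort censoring level). Coefficient settings are
  i.i.d. Gaussian with SD 2 — large enough that cluster composition carries a
  clear prognostic signal; the "strong-signal" setting used for the
  generalisation check is the fixed vector $(3, -3, 1.5, -1.5, 0)$.
- `relabel_clusters()` produces deliberately mismatched labels (merging
  neighbouring clusters, or splitting each at the median of a random
  projection of its log1p expression) to emulate annotation boundaries that
  do not coincide with the populations driving a signal.

What the simulation does *not* emulate: zero inflation and ambient
contamination, gene-gene correlation beyond cluster/batch structure, library
-size gradients within clusters, informative censoring, and real spatial
autocorrelation (spots are grid-placed pseudo-mixtures). Passing the
benchmark therefore demonstrates the estimator's correctness and its
statistical behaviour under its own model class, not robustness to every
artefact of real data.

Problem sizes in the test-suite and in `scripts/acceptance.R` follow this
design (300 pseudo-bulk samples; 10 coefficient settings; 20 resampled
splits; 100 permutations), which keeps a full verification run to a few
minutes on one CPU while leaving the statistical conclusions stable across
seeds.

## Degenerate inputs and numerical notes

- Zero-length or single-cluster references, fractions/labels of mismatched
  length, empty gene intersections, all-censored cohorts, and time grids on
  which the censoring estimate vanishes are all rejected with explicit
  errors rather than propagated.
- Partial likelihoods subtract the max of $\eta$ before exponentiating; the
  Breslow baseline undoes the shift so it pairs with raw $\eta$.
- A cluster with a single cell cannot be permuted; its importance is defined
  as 0 with a warning.
- All file formats are plain text (MTX + TSV triplet, CSV); on-disk tables
  always carry explicit string identifiers. HDF5-based containers are out of
  scope.
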