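# Shared fixtures, built once per test run and cached. The "study" fixture is
# the benchmark design: a 500-cell / 200-gene / 5-cluster / 2-batch reference
# split in half, 300 pseudo-bulk samples mixed from one half with Dirichlet(1)
# cluster proportions, and a strong-signal survival setting with per-cluster
# coefficients (3, -3, 1.5, -1.5, 0) and 30% censoring.

.fixture_cache <- new.env(parent = emptyenv())

strong_coefficients <- function() c(3, -3, 1.5, -1.5, 0)

study_fixture <- function() {
  if (is.null(.fixture_cache$study)) {
    sim <- simulate_reference(seed = 101)
    halves <- split_reference(sim$reference, fraction = 0.5, seed = 102)
    pb <- simulate_pseudobulk(halves$bulk_source, seed = 103)
    vae <- fit_vae(halves$reference, seed = 104)
    deconv <- fit_deconvolution(pb$counts, vae, seed = 105)
    survival <- simulate_survival(
      pb$true_proportions, strong_coefficients(),
      censor_fraction = 0.3, seed = 106
    )
    .fixture_cache$study <- list(
      sim = sim, reference = halves$reference, source = halves$bulk_source,
      pseudobulk = pb, vae = vae, deconv = deconv, survival = survival
    )
  }
  .fixture_cache$study
}

study_hazard <- function() {
  if (is.null(.fixture_cache$study_hazard)) {
    fx <- study_fixture()
    .fixture_cache$study_hazard <- fit_hazard(fx$deconv, fx$survival, seed = 107)
  }
  .fixture_cache$study_hazard
}

# Small, fast fixture for structural unit tests.
tiny_fixture <- function() {
  if (is.null(.fixture_cache$tiny)) {
    sim <- simulate_reference(
      n_cells = 150, n_genes = 60, n_clusters = 3, n_batches = 2, seed = 11
    )
    halves <- split_reference(sim$reference, fraction = 0.5, seed = 12)
    pb <- simulate_pseudobulk(
      halves$bulk_source,
      n_bulk = 60, cells_per_sample = 300, seed = 13
    )
    vae <- fit_vae(
      halves$reference,
      latent_dim = 6, hidden = c(32, 32), max_epochs = 80, seed = 14
    )
    deconv <- fit_deconvolution(pb$counts, vae, max_epochs = 800, seed = 15)
    survival <- simulate_survival(
      pb$true_proportions, c(2, -2, 0),
      censor_fraction = 0.3, seed = 16
    )
    .fixture_cache$tiny <- list(
      sim = sim, reference = halves$reference, source = halves$bulk_source,
      pseudobulk = pb, vae = vae, deconv = deconv, survival = survival
    )
  }
  .fixture_cache$tiny
}

# Random survival data with tied event times, for the oracle comparisons.
random_tied_survival <- function(n, seed) {
  cellhazard:::with_seed(seed, {
    survival_table(tibble::tibble(
      sample_id = paste0("s", seq_len(n)),
      time = sample(1:8, n, replace = TRUE),
      event = rbinom(n, 1, 0.7)
    ))
  })
}

# Partial log-likelihood at a fixed linear predictor via survival::coxph:
# a single covariate equal to eta, coefficient pinned at 1, zero iterations.
coxph_loglik_at <- function(eta, survival, ties) {
  fit <- survival::coxph(
    survival::Surv(survival$time, survival$event) ~ eta,
    init = 1, ties = ties,
    control = survival::coxph.control(iter.max = 0)
  )
  fit$loglik[2]
}
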