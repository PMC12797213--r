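make_fraction_matrix <- function(n_cells, n_samples, seed) {
  cellhazard:::with_seed(seed, {
    m <- matrix(rgamma(n_cells * n_samples, 0.5), n_cells, n_samples)
    m <- sweep(m, 2, colSums(m), "/")
    dimnames(m) <- list(
      paste0("cell_", seq_len(n_cells)),
      paste0("sample_", seq_len(n_samples))
    )
    m
  })
}

test_that("permutation importance is zero for constant-contribution clusters", {
  m <- make_fraction_matrix(30, 80, seed = 1)
  labels <- rep(c("A", "B", "C"), each = 10)
  beta <- c(cellhazard:::with_seed(99, rnorm(10)), rep(0.7, 10), rep(-0.2, 10)) # B, C constant
  surv <- simulate_survival(matrix(drop(crossprod(m, beta))), 1,
    censor_fraction = 0.2, seed = 2
  )
  surv$sample_id <- colnames(m)
  rep <- permutation_importance(beta, m, labels, surv, n_perm = 20, seed = 3)
  expect_identical(rep$decrement[rep$cluster == "B"], 0)
  expect_identical(rep$decrement[rep$cluster == "C"], 0)
  expect_identical(rep$se[rep$cluster == "B"], 0)
  expect_error(permutation_importance(beta, m, labels, surv, n_perm = 0), "n_perm")
})

test_that("a signal-free cluster's expected decrement is zero within Monte-Carlo error", {
  # contributions unrelated to survival: the decrement averages to zero over
  # independently drawn datasets (within each dataset the baseline c-index is
  # itself a draw from the null, so the expectation is over datasets).
  decs <- vapply(1:30, function(d) {
    m <- make_fraction_matrix(20, 60, seed = 400 + d)
    beta <- cellhazard:::with_seed(500 + d, rnorm(20))
    surv <- cellhazard:::with_seed(600 + d, {
      survival_table(tibble::tibble(
        sample_id = colnames(m),
        time = rexp(60),
        event = rbinom(60, 1, 0.75)
      ))
    })
    rep <- permutation_importance(beta, m, rep("noise", 20), surv,
      n_perm = 10, seed = 700 + d
    )
    rep$decrement
  }, numeric(1))
  expect_lt(abs(mean(decs)), 2 * sd(decs) / sqrt(length(decs)))
})

test_that("treating all cells as one cluster equals a global shuffle", {
  m <- make_fraction_matrix(25, 60, seed = 8)
  beta <- cellhazard:::with_seed(9, rnorm(25))
  surv <- simulate_survival(matrix(drop(crossprod(m, beta))), 1,
    censor_fraction = 0, seed = 10
  )
  surv$sample_id <- colnames(m)
  rep <- permutation_importance(beta, m, rep("all", 25), surv, n_perm = 15, seed = 11)

  # replay the same RNG stream with an explicit global shuffle
  eta0 <- drop(crossprod(m, beta))
  base <- concordance_index(eta0, surv)
  dec <- cellhazard:::with_seed(11, {
    vapply(1:15, function(p) {
      perm <- sample(seq_len(25))
      base - concordance_index(drop(crossprod(m, beta[perm])), surv)
    }, numeric(1))
  })
  expect_equal(rep$decrement, mean(dec), tolerance = 1e-12)

  # single-cell cluster: decrement defined as 0 with a warning
  labels1 <- c("solo", rep("rest", 24))
  expect_warning(
    rep1 <- permutation_importance(beta, m, labels1, surv, n_perm = 3, seed = 12),
    "single cell"
  )
  expect_identical(rep1$decrement[rep1$cluster == "solo"], 0)
})

test_that("gene-contribution correlations rank linear relationships exactly", {
  cellhazard:::with_seed(13, {
    beta <- rnorm(50)
    X <- matrix(rgamma(50 * 70, 2), 50, 70)
    colnames(X) <- paste0("g", 1:70)
    X[, 1] <- 2 * beta + 3 # perfectly positive
    X[, 2] <- -beta + 1 # perfectly negative
    X[, 3] <- 5 # zero variance
    tab <- gene_contribution_correlation(X, beta, top_k = 30)
    expect_equal(tab$r[tab$gene == "g1"], 1, tolerance = 1e-12)
    expect_equal(tab$r[tab$gene == "g2"], -1, tolerance = 1e-12)
    expect_identical(tab$r[tab$gene == "g3"], 0)
    expect_true(tab$zero_variance[tab$gene == "g3"])
    expect_identical(sum(tab$selection == "top", na.rm = TRUE), 30L)
    expect_identical(sum(tab$selection == "bottom", na.rm = TRUE), 30L)
    expect_identical(tab$gene[tab$rank == 1], "g1")
    expect_true(all(tab$r >= -1 & tab$r <= 1))
  })
})

test_that("quantile clipping uses linear interpolation and is idempotent", {
  x <- 0:100
  clipped <- cellhazard:::clip_quantiles(x)
  expect_equal(range(clipped), c(2.5, 97.5), tolerance = 1e-12)
  # clipping against the raw reference is a projection, hence idempotent
  expect_identical(cellhazard:::clip_quantiles(clipped, reference = x), clipped)
})

test_that("spatial hazard scores are fraction-weighted contributions", {
  fake_spot_fit <- function(m, coords = NULL) {
    structure(
      list(
        fractions = m, sample_id = colnames(m), cell_id = rownames(m),
        coordinates = coords, type = "spot"
      ),
      class = "deconv_fit"
    )
  }
  m <- diag(4)
  dimnames(m) <- list(paste0("cell_", 1:4), paste0("spot_", 1:4))
  beta <- c(0.5, -1, 2, 0)
  map <- spatial_hazard(fake_spot_fit(m), beta)
  expect_equal(map$hazard, beta) # fraction 1 on one cell: score is its beta

  # equal contributions: every spot scores the common value
  m2 <- make_fraction_matrix(10, 6, seed = 14)
  map2 <- spatial_hazard(fake_spot_fit(m2), rep(1.3, 10))
  expect_equal(map2$hazard, rep(1.3, 6), tolerance = 1e-12)
  expect_true(all(
    map2$hazard_clipped >= quantile(map2$hazard, 0.025) - 1e-12 &
      map2$hazard_clipped <= quantile(map2$hazard, 0.975) + 1e-12
  ))
  expect_error(spatial_hazard(fake_spot_fit(m2), beta), "per reference cell")
})

test_that("spot-group means are order-invariant and ranked", {
  map <- tibble::tibble(
    spot_id = paste0("s", 1:4),
    hazard = c(1, 1, 3, 3),
    hazard_clipped = c(1, 1, 3, 3)
  )
  g <- spot_group_mean_hazard(map, c("g1", "g1", "g2", "g2"))
  expect_equal(g$mean_hazard[g$group == "g1"], 1)
  expect_equal(g$mean_hazard[g$group == "g2"], 3)
  expect_identical(g$group[g$rank == 1], "g2")

  # one group: mean equals the global mean
  g1 <- spot_group_mean_hazard(map, rep("all", 4))
  expect_equal(g1$mean_hazard, mean(map$hazard))

  # permuting spot order leaves group means unchanged
  perm <- c(3, 1, 4, 2)
  g2 <- spot_group_mean_hazard(map[perm, ], c("g2", "g1", "g2", "g1"))
  expect_equal(g2, g)

  expect_error(
    spot_group_mean_hazard(map, factor(rep("a", 4), levels = c("a", "b"))),
    "empty"
  )
})

test_that("cross-dataset similarity is a correlation matrix over shared genes", {
  cellhazard:::with_seed(15, {
    genes <- paste0("g", 1:40)
    t1 <- tibble::tibble(gene = genes, r = rnorm(40))
    t2 <- tibble::tibble(gene = rev(genes), r = rnorm(40))
    t3 <- tibble::tibble(gene = genes, r = -t1$r)
    sim <- cross_dataset_similarity(list(a = t1, b = t2, c = t3))
    expect_equal(unname(diag(sim)), rep(1, 3), tolerance = 1e-12)
    expect_equal(sim["a", "c"], -1, tolerance = 1e-12)
    expect_equal(sim, t(sim), tolerance = 1e-12)
    expect_error(
      cross_dataset_similarity(list(t1[1:5, ], t2[1:5, ])),
      "shared genes"
    )
    expect_error(cross_dataset_similarity(list(t1)), "two")
  })
})
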