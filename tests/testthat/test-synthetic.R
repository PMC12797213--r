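test_that("simulate_reference honours shape, partition, and determinism contracts", {
  sim <- simulate_reference(
    n_cells = 500, n_genes = 200, n_clusters = 5, n_batches = 2, seed = 0
  )
  ref <- sim$reference
  expect_identical(dim(ref$counts), c(500L, 200L))
  expect_true(all(ref$counts >= 0 & ref$counts == round(ref$counts)))
  expect_identical(nlevels(ref$cluster), 5L)
  expect_true(all(table(ref$cluster) > 0))
  expect_true(all(table(ref$batch) > 0))
  # cluster mean profiles pairwise distinct
  lm <- sim$truth$cluster_log_means
  d <- as.matrix(dist(lm))
  expect_true(all(d[upper.tri(d)] > 0))
  # library mean is the row mean of counts
  expect_equal(ref$library_mean, rowMeans(ref$counts), tolerance = 1e-12)

  again <- simulate_reference(
    n_cells = 500, n_genes = 200, n_clusters = 5, n_batches = 2, seed = 0
  )
  expect_identical(again$reference$counts, ref$counts)
  expect_identical(again$reference$cluster, ref$cluster)

  expect_error(simulate_reference(n_clusters = 1), "n_clusters")
  expect_error(simulate_reference(n_cells = 3, n_clusters = 5), "n_cells")
})

test_that("split_reference partitions cells exhaustively, stratified by cluster", {
  sim <- simulate_reference(n_cells = 200, n_genes = 50, seed = 2)
  halves <- split_reference(sim$reference, fraction = 0.5, seed = 3)
  ids <- c(halves$reference$cell_id, halves$bulk_source$cell_id)
  expect_setequal(ids, sim$reference$cell_id)
  expect_length(ids, 200)
  expect_setequal(levels(halves$reference$cluster), levels(sim$reference$cluster))
  expect_true(all(table(halves$reference$cluster) > 0))
  expect_true(all(table(halves$bulk_source$cluster) > 0))
  expect_equal(nrow(halves$reference$counts), 100, tolerance = 0.05)

  rep2 <- split_reference(sim$reference, fraction = 0.5, seed = 3)
  expect_identical(rep2$reference$cell_id, halves$reference$cell_id)

  tiny <- sim$reference[1:6]
  tiny$cluster <- factor(c("a", "a", "a", "a", "a", "lone"))
  expect_error(split_reference(tiny, 0.5), "lone")
  expect_error(split_reference(sim$reference, fraction = 1), "fraction")
})

test_that("pseudo-bulk samples are proportion-weighted aggregates of cluster cells", {
  # Hand-built reference: cluster A expresses only gene g1, cluster B only g2.
  counts <- rbind(c(5, 0), c(3, 0), c(0, 4), c(0, 7))
  rownames(counts) <- paste0("c", 1:4)
  colnames(counts) <- c("g1", "g2")
  ref <- cell_reference(counts, batch = rep("b1", 4), cluster = c("A", "A", "B", "B"))
  pb <- simulate_pseudobulk(
    ref,
    n_bulk = 2, cells_per_sample = 50,
    proportions = rbind(c(1, 0), c(0, 1)), seed = 5
  )
  expect_identical(pb$counts["sample_1", "g2"], 0) # pure-A sample: no B counts
  expect_identical(pb$counts["sample_2", "g1"], 0)
  expect_true(all(pb$counts >= 0 & pb$counts == round(pb$counts)))
  expect_equal(rowSums(pb$true_proportions), c(sample_1 = 1, sample_2 = 1))
})

test_that("pseudo-bulk gene means approach the analytic mixture of cluster means", {
  sim <- simulate_reference(n_cells = 400, n_genes = 80, n_clusters = 4, seed = 7)
  ref <- sim$reference
  pb <- simulate_pseudobulk(ref, n_bulk = 40, cells_per_sample = 1000, seed = 8)
  # Analytic per-cluster mean profiles over the cells actually sampled from.
  cl_means <- rowsum(sim$truth$expected_mean, ref$cluster) /
    as.vector(table(ref$cluster))
  expected <- pb$true_proportions %*% cl_means[levels(ref$cluster), ] * 1000
  total_obs <- colSums(pb$counts)
  total_exp <- colSums(expected)
  rel_err <- abs(total_obs - total_exp) / total_exp
  expect_lt(mean(rel_err), 0.05)
  expect_gt(cor(total_obs, total_exp), 0.99)
})

test_that("simulated survival follows the constant-baseline Cox model", {
  # eta = 0 everywhere: times are Exp(1), mean 1.
  P <- matrix(1 / 3, 10000, 3)
  st <- simulate_survival(P, c(0, 0, 0), baseline_rate = 1, censor_fraction = 0, seed = 9)
  expect_true(all(st$event == 1L))
  expect_true(all(st$time > 0))
  expect_gt(mean(st$time), 0.95)
  expect_lt(mean(st$time), 1.05)
  expect_equal(attr(st, "eta"), rep(0, 10000))

  # censoring fraction is hit within binomial error
  st2 <- simulate_survival(P, c(0, 0, 0), censor_fraction = 0.4, seed = 10)
  se <- sqrt(0.4 * 0.6 / 10000)
  expect_lt(abs(mean(1 - st2$event) - 0.4), 4 * se)

  # doubling a cluster-heavy coefficient shifts that sample's times down
  P1 <- matrix(c(1, 0), 1000, 2, byrow = TRUE)
  t1 <- simulate_survival(P1, c(1, 0), censor_fraction = 0, seed = 11)$time
  t2 <- simulate_survival(P1, c(2, 0), censor_fraction = 0, seed = 12)$time
  expect_gt(mean(t1), mean(t2))

  expect_error(simulate_survival(P, c(0, 0, 0), censor_fraction = 1), "censor_fraction")
  expect_error(simulate_survival(P, c(0, 0)), "coefficients")
})

test_that("coefficient settings are seeded draws of the stated size", {
  s <- sample_coefficient_settings(100, n_clusters = 5, seed = 20)
  expect_length(s, 100)
  expect_true(all(vapply(s, length, integer(1)) == 5))
  expect_identical(s, sample_coefficient_settings(100, n_clusters = 5, seed = 20))
  expect_length(sample_coefficient_settings(1, 3, seed = 1), 1)
  expect_error(sample_coefficient_settings(0, 3), "n_settings")
})

test_that("relabel_clusters merges or splits cluster boundaries", {
  sim <- simulate_reference(n_cells = 120, n_genes = 40, n_clusters = 4, seed = 21)
  merged <- relabel_clusters(sim$reference, "merge")
  expect_identical(nlevels(merged$cluster), 2L)
  split <- relabel_clusters(sim$reference, "split", seed = 22)
  expect_identical(nlevels(split$cluster), 8L)
  expect_length(split$cluster, 120)
  # split refines the original partition
  tab <- table(split$cluster, sim$reference$cluster)
  expect_true(all(rowSums(tab > 0) == 1))
})

test_that("simulated spots sit on a grid with simplex proportions", {
  sim <- simulate_reference(n_cells = 100, n_genes = 30, n_clusters = 3, seed = 23)
  sp <- simulate_spots(sim$reference, n_spots = 9, seed = 24)
  expect_identical(nrow(sp$counts), 9L)
  expect_equal(unname(rowSums(sp$true_proportions)), rep(1, 9))
  expect_identical(nrow(sp$coordinates), 9L)
  expect_true(all(sp$coordinates$x >= 0 & sp$coordinates$y >= 0))
})
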