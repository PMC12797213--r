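# Simulation module: clustered single-cell references, pseudo-bulk mixtures
# with known cluster proportions, and survival times generated from a Cox
# proportional-hazards model with a constant baseline hazard. These are the
# benchmark conditions under which deconvolution and hazard-contribution
# recovery are validated.

#' Simulate a clustered single-cell reference
#'
#' Generates raw counts for `n_cells` cells in `n_clusters` clusters across
#' `n_batches` batches. Each cluster has a gene-wise log-mean profile drawn
#' from a Gaussian around a shared baseline; each batch adds a gene-wise
#' additive log-offset; counts are negative binomial with fixed
#' inverse-dispersion. This keeps the mixture mean of any cluster blend in
#' closed form, so pseudo-bulk expectations can be checked analytically.
#'
#' @param n_cells,n_genes,n_clusters,n_batches Problem sizes. `n_clusters >= 2`,
#'   `n_cells >= n_clusters`, `n_batches >= 1`.
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @param base_logmean Baseline log mean count per gene (default `log(2)`).
#' @param cluster_sd SD of the gene-wise cluster log-mean deviations.
#' @param batch_sd SD of the gene-wise additive batch log-offsets.
#' @param dispersion Negative-binomial inverse-dispersion (the `size`
#'   parameter); counts have variance `mu + mu^2 / dispersion`.
#' @return A list with `reference` (a [cell_reference()] with cluster labels)
#'   and `truth`, a list carrying `cluster_log_means` (clusters x genes),
#'   `batch_offsets` (batches x genes), `expected_mean` (cells x genes NB
#'   means), `dispersion`, and `seed`.
#' @examples
#' sim <- simulate_reference(n_cells = 100, n_genes = 40, n_clusters = 3,
#'                           n_batches = 2, seed = 1)
#' sim$reference
#' @export
simulate_reference <- function(n_cells = 500, n_genes = 200, n_clusters = 5,
                               n_batches = 2, seed = 1,
                               base_logmean = log(2), cluster_sd = 1,
                               batch_sd = 0.2, dispersion = 10) {
  if (n_clusters < 2) abort("`n_clusters` must be at least 2.")
  if (n_cells < n_clusters) abort("`n_cells` must be at least `n_clusters`.")
  if (n_batches < 1) abort("`n_batches` must be at least 1.")
  with_seed(seed, {
    base <- rnorm(n_genes, base_logmean, 0.3)
    cl_dev <- matrix(rnorm(n_clusters * n_genes, 0, cluster_sd), n_clusters, n_genes)
    batch_off <- matrix(rnorm(n_batches * n_genes, 0, batch_sd), n_batches, n_genes)
    cluster_log_means <- sweep(cl_dev, 2, base, "+")

    # Guarantee every cluster and batch is non-empty.
    cl <- c(seq_len(n_clusters), sample.int(n_clusters, n_cells - n_clusters, replace = TRUE))
    cl <- cl[sample.int(n_cells)]
    bt <- c(seq_len(n_batches), sample.int(n_batches, n_cells - n_batches, replace = TRUE))
    bt <- bt[sample.int(n_cells)]

    mu <- exp(cluster_log_means[cl, , drop = FALSE] + batch_off[bt, , drop = FALSE])
    counts <- matrix(
      stats::rnbinom(n_cells * n_genes, size = dispersion, mu = mu),
      n_cells, n_genes
    )
    rownames(counts) <- paste0("cell_", seq_len(n_cells))
    colnames(counts) <- paste0("gene_", seq_len(n_genes))
    rownames(cluster_log_means) <- paste0("cluster_", seq_len(n_clusters))
    colnames(cluster_log_means) <- colnames(counts)

    ref <- cell_reference(
      counts,
      batch = paste0("batch_", bt),
      cluster = paste0("cluster_", cl)
    )
    list(
      reference = ref,
      truth = list(
        cluster_log_means = cluster_log_means,
        batch_offsets = batch_off,
        expected_mean = mu,
        dispersion = dispersion,
        seed = seed
      )
    )
  })
}

#' Split a reference into reference and pseudo-bulk source halves
#'
#' Partitions the cells into two disjoint, exhaustive subsets, stratified by
#' cluster so that both halves contain every cluster. One half serves as the
#' model's reference; the other is reserved for building pseudo-bulk samples,
#' so the benchmark never deconvolves a sample against the very cells that
#' produced it.
#'
#' @param reference A [cell_reference()] with cluster labels.
#' @param fraction Fraction of each cluster assigned to the reference half
#'   (strictly between 0 and 1).
#' @param seed Integer seed.
#' @return A list with `reference` and `bulk_source`, both `cell_reference`s.
#' @export
split_reference <- function(reference, fraction = 0.5, seed = 1) {
  if (!inherits(reference, "cell_reference")) abort("`reference` must be a cell_reference.")
  if (is.null(reference$cluster)) abort("`reference` must carry cluster labels.")
  if (!(fraction > 0 && fraction < 1)) abort("`fraction` must lie strictly between 0 and 1.")
  sizes <- table(reference$cluster)
  small <- names(sizes)[sizes < 2]
  if (length(small)) {
    abort(sprintf(
      "cluster(s) with fewer than 2 cells cannot be split: %s",
      paste(small, collapse = ", ")
    ))
  }
  with_seed(seed, {
    take <- logical(length(reference$cluster))
    for (k in levels(reference$cluster)) {
      idx <- which(reference$cluster == k)
      n_ref <- min(max(round(fraction * length(idx)), 1L), length(idx) - 1L)
      take[sample(idx, n_ref)] <- TRUE
    }
    list(reference = reference[take], bulk_source = reference[!take])
  })
}

# Dirichlet draws, rows on the simplex.
rdirichlet <- function(n, alpha) {
  g <- matrix(rgamma(n * length(alpha), shape = alpha), n, length(alpha), byrow = TRUE)
  g / rowSums(g)
}

#' Generate pseudo-bulk samples with known cluster proportions
#'
#' For each pseudo-bulk sample, cluster proportions are drawn from a
#' symmetric Dirichlet, `cells_per_sample` cells are drawn (with replacement,
#' multinomially across clusters according to the proportions) from the
#' source half, and their raw counts are summed.
#'
#' @param source A [cell_reference()] with cluster labels (the pseudo-bulk
#'   half from [split_reference()]).
#' @param n_bulk Number of pseudo-bulk samples.
#' @param concentration Symmetric Dirichlet concentration for the random
#'   cluster proportions.
#' @param cells_per_sample Number of cell draws aggregated per sample.
#' @param proportions Optional matrix (`n_bulk` x clusters) of fixed
#'   proportions; overrides the Dirichlet draw (rows must sum to 1).
#' @param seed Integer seed.
#' @return A list with `counts` (samples x genes integer matrix),
#'   `true_proportions` (samples x clusters, rows summing to 1), and
#'   `sample_id`.
#' @export
simulate_pseudobulk <- function(source, n_bulk = 300, concentration = 1,
                                cells_per_sample = 1000, proportions = NULL,
                                seed = 1) {
  if (!inherits(source, "cell_reference")) abort("`source` must be a cell_reference.")
  if (is.null(source$cluster)) abort("`source` must carry cluster labels.")
  if (n_bulk < 1) abort("`n_bulk` must be at least 1.")
  if (concentration <= 0) abort("`concentration` must be positive.")
  lev <- levels(source$cluster)
  empty <- lev[!lev %in% unique(as.character(source$cluster))]
  if (length(empty)) {
    abort(sprintf("source half has empty cluster(s): %s", paste(empty, collapse = ", ")))
  }
  cl_idx <- split(seq_along(source$cluster), source$cluster)
  with_seed(seed, {
    if (is.null(proportions)) {
      proportions <- rdirichlet(n_bulk, rep(concentration, length(lev)))
    } else {
      proportions <- as.matrix(proportions)
      if (nrow(proportions) != n_bulk || ncol(proportions) != length(lev)) {
        abort("`proportions` must be n_bulk x n_clusters.")
      }
      if (any(abs(rowSums(proportions) - 1) > 1e-9)) {
        abort("rows of `proportions` must sum to 1.")
      }
    }
    colnames(proportions) <- lev
    rownames(proportions) <- paste0("sample_", seq_len(n_bulk))

    weights <- matrix(0, n_bulk, nrow(source$counts))
    for (b in seq_len(n_bulk)) {
      n_k <- drop(stats::rmultinom(1, cells_per_sample, proportions[b, ]))
      for (k in seq_along(lev)) {
        if (n_k[k] == 0) next
        pick <- sample(cl_idx[[k]], n_k[k], replace = TRUE)
        tab <- tabulate(pick, nbins = nrow(source$counts))
        weights[b, ] <- weights[b, ] + tab
      }
    }
    counts <- weights %*% source$counts
    rownames(counts) <- rownames(proportions)
    colnames(counts) <- source$gene
    list(
      counts = counts,
      true_proportions = proportions,
      sample_id = rownames(proportions)
    )
  })
}

#' Simulate survival times from a Cox model with constant baseline hazard
#'
#' The per-sample linear predictor is `eta = proportions %*% coefficients`;
#' event times are drawn by inverse transform from the implied exponential
#' distribution, `T = -log(U) / (baseline_rate * exp(eta))`. Censoring is
#' independent exponential, with its rate calibrated by bisection so the
#' expected censored fraction matches `censor_fraction`.
#'
#' @param true_proportions Samples x clusters matrix, rows summing to 1.
#' @param coefficients Per-cluster hazard coefficients (length = clusters).
#' @param baseline_rate Constant baseline hazard (> 0).
#' @param censor_fraction Target expected fraction of censored samples, in
#'   `[0, 1)`.
#' @param seed Integer seed.
#' @return A [survival_table()] with columns `sample_id`, `time`, `event`;
#'   the true linear predictor is attached as attribute `"eta"`.
#' @export
simulate_survival <- function(true_proportions, coefficients, baseline_rate = 1,
                              censor_fraction = 0.3, seed = 1) {
  P <- as.matrix(true_proportions)
  if (length(coefficients) != ncol(P)) {
    abort("`coefficients` must have one entry per cluster (column of proportions).")
  }
  if (baseline_rate <= 0) abort("`baseline_rate` must be positive.")
  if (censor_fraction < 0 || censor_fraction >= 1) {
    abort("`censor_fraction` must lie in [0, 1).")
  }
  eta <- drop(P %*% coefficients)
  with_seed(seed, {
    u <- runif(nrow(P))
    t_event <- -log(u) / (baseline_rate * exp(eta))
    if (censor_fraction == 0) {
      time <- t_event
      event <- rep(1L, nrow(P))
    } else {
      # P(censored | rate) = E[1 - exp(-rate * T_event)]; monotone in rate.
      target <- function(rate) mean(1 - exp(-rate * t_event)) - censor_fraction
      hi <- 1 / stats::median(t_event)
      while (target(hi) < 0) hi <- hi * 2
      rate <- stats::uniroot(target, c(1e-12, hi), tol = 1e-10)$root
      t_cens <- stats::rexp(nrow(P), rate)
      time <- pmin(t_event, t_cens)
      event <- as.integer(t_event <= t_cens)
    }
    out <- survival_table(tibble::tibble(
      sample_id = rownames(P) %||% paste0("sample_", seq_len(nrow(P))),
      time = time,
      event = event
    ))
    attr(out, "eta") <- eta
    out
  })
}

#' Draw random per-cluster hazard coefficient settings
#'
#' Each setting is an i.i.d. Gaussian coefficient vector, one entry per
#' cluster, used to vary the survival-time generating process across
#' benchmark datasets built from the same pseudo-bulk samples.
#'
#' @param n_settings Number of settings (>= 1).
#' @param n_clusters Number of clusters per setting.
#' @param sd Standard deviation of the Gaussian coefficients.
#' @param seed Integer seed.
#' @return A list of `n_settings` numeric vectors of length `n_clusters`.
#' @export
sample_coefficient_settings <- function(n_settings, n_clusters, sd = 2, seed = 1) {
  if (n_settings < 1) abort("`n_settings` must be at least 1.")
  with_seed(seed, {
    lapply(seq_len(n_settings), function(i) rnorm(n_clusters, 0, sd))
  })
}

#' Perturb cluster labels by merging or splitting clusters
#'
#' Produces a label set with boundaries deliberately different from the
#' generating clusters, emulating the mismatch between annotation and the
#' populations that actually drive a signal. `"merge"` joins consecutive
#' cluster pairs; `"split"` divides each cluster in two at the median of a
#' random linear projection of its log1p expression.
#'
#' @param reference A [cell_reference()] with cluster labels.
#' @param action `"merge"` or `"split"`.
#' @param seed Integer seed (used by `"split"`).
#' @return A `cell_reference` with the perturbed cluster labels.
#' @export
relabel_clusters <- function(reference, action = c("merge", "split"), seed = 1) {
  action <- match.arg(action)
  if (is.null(reference$cluster)) abort("`reference` must carry cluster labels.")
  lev <- levels(reference$cluster)
  labels <- as.character(reference$cluster)
  if (action == "merge") {
    pair_of <- function(i) {
      j <- if (i %% 2 == 0) i - 1L else min(i + 1L, length(lev))
      paste(sort(c(lev[i], lev[j]))[1], sort(c(lev[i], lev[j]))[2], sep = "+")
    }
    map <- vapply(seq_along(lev), pair_of, character(1))
    names(map) <- lev
    labels <- map[labels]
  } else {
    with_seed(seed, {
      lx <- log1p(reference$counts)
      for (k in lev) {
        idx <- which(labels == k)
        v <- rnorm(ncol(lx))
        s <- drop(lx[idx, , drop = FALSE] %*% v)
        labels[idx] <- paste0(k, ifelse(s > stats::median(s), "a", "b"))
      }
    })
  }
  reference$cluster <- factor(labels)
  reference
}

#' Simulate spatial spots on a uniform grid
#'
#' Each spot is a small pseudo-bulk aggregate (few cell draws, sparse
#' Dirichlet proportions), placed on a uniform grid of coordinates.
#'
#' @inheritParams simulate_pseudobulk
#' @param n_spots Number of spots.
#' @param cells_per_spot Cell draws aggregated per spot.
#' @return A list with `counts` (spots x genes), `coordinates` (tibble:
#'   `spot_id`, `x`, `y`), `true_proportions`, and `spot_id`.
#' @export
simulate_spots <- function(source, n_spots = 100, concentration = 0.3,
                           cells_per_spot = 20, proportions = NULL, seed = 1) {
  pb <- simulate_pseudobulk(
    source,
    n_bulk = n_spots, concentration = concentration,
    cells_per_sample = cells_per_spot, proportions = proportions, seed = seed
  )
  spot_id <- sub("^sample_", "spot_", pb$sample_id)
  rownames(pb$counts) <- spot_id
  rownames(pb$true_proportions) <- spot_id
  side <- ceiling(sqrt(n_spots))
  coords <- tibble::tibble(
    spot_id = spot_id,
    x = (seq_len(n_spots) - 1L) %% side,
    y = (seq_len(n_spots) - 1L) %/% side
  )
  list(
    counts = pb$counts,
    coordinates = coords,
    true_proportions = pb$true_proportions,
    spot_id = spot_id
  )
}
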