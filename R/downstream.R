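# Post-fit analyses: within-cluster permutation importance of the hazard
# contributions, gene-contribution correlation ranking, spatial hazard
# mapping with display clipping, and cross-dataset similarity.

resolve_contributions <- function(contributions) {
  if (inherits(contributions, "hazard_fit")) contributions$beta else contributions
}

#' Within-cluster permutation importance of hazard contributions
#'
#' For each cluster, the per-cell contributions are shuffled among that
#' cluster's cells (all other cells fixed), the per-sample linear predictor
#' and concordance index are recomputed, and the mean decrement from the
#' baseline c-index over `n_perm` permutations is reported. A cluster whose
#' cells share one contribution value is untouched by permutation and scores
#' exactly 0.
#'
#' @param contributions Per-cell contributions (numeric, one per cell) or a
#'   [fit_hazard()] object.
#' @param fractions Cell-fraction matrix (cells x samples).
#' @param cluster_labels Per-cell cluster labels covering every cell.
#' @param survival A [survival_table()] aligned with the fraction columns.
#' @param n_perm Number of permutations per cluster (>= 1).
#' @param seed Integer seed.
#' @param samples Optional subset of samples (ids or indices) on which to
#'   evaluate the c-index; defaults to the full cohort.
#' @return A tibble of class `permutation_report` with one row per cluster:
#'   `cluster`, `decrement` (baseline minus mean permuted c-index), `se`
#'   (standard error over permutations), `n_cells`. Baseline c-index, `n_perm`
#'   and `seed` are attached as attributes.
#' @export
permutation_importance <- function(contributions, fractions, cluster_labels,
                                   survival, n_perm = 10, seed = 1,
                                   samples = NULL) {
  beta <- resolve_contributions(contributions)
  if (inherits(contributions, "hazard_fit")) {
    cluster_labels <- cluster_labels %||% contributions$cluster
  }
  if (n_perm < 1) abort("`n_perm` must be at least 1.")
  if (length(cluster_labels) != nrow(fractions) || anyNA(cluster_labels)) {
    abort("`cluster_labels` must cover every cell.")
  }
  if (!inherits(survival, "survival_table")) survival <- survival_table(survival)
  if (!is.null(samples)) {
    keep <- if (is.character(samples)) match(samples, colnames(fractions)) else samples
    fractions <- fractions[, keep, drop = FALSE]
  }
  if (!is.null(colnames(fractions))) {
    survival <- survival[match(colnames(fractions), survival$sample_id), ]
  }
  eta0 <- drop(crossprod(fractions, beta))
  baseline <- concordance_index(eta0, survival)
  labels <- factor(cluster_labels)

  out <- with_seed(seed, {
    purrr::map(levels(labels), function(k) {
      idx <- which(labels == k)
      if (length(idx) == 1) {
        warn(sprintf("cluster '%s' has a single cell; decrement set to 0.", k))
        return(tibble::tibble(
          cluster = k, decrement = 0, se = 0, n_cells = 1L
        ))
      }
      dec <- vapply(seq_len(n_perm), function(p) {
        perm <- sample(idx)
        # eta changes only through the permuted cluster's rows.
        eta_p <- eta0 + drop(crossprod(
          fractions[idx, , drop = FALSE],
          beta[perm] - beta[idx]
        ))
        baseline - concordance_index(eta_p, survival)
      }, numeric(1))
      tibble::tibble(
        cluster = k,
        decrement = mean(dec),
        se = if (n_perm > 1) sd(dec) / sqrt(n_perm) else 0,
        n_cells = length(idx)
      )
    })
  })
  report <- dplyr::bind_rows(out)
  attr(report, "baseline_cindex") <- baseline
  attr(report, "n_perm") <- n_perm
  attr(report, "seed") <- seed
  class(report) <- c("permutation_report", class(report))
  report
}

#' Correlate reconstructed gene expression with hazard contributions
#'
#' For each gene, the Pearson correlation across cells between the decoder's
#' reconstructed expression and the per-cell hazard contribution is computed
#' (optionally on a cell subset, e.g. one cell type). Genes with zero
#' expression variance get `r = 0` and are flagged. The `top_k` most
#' positively and most negatively correlated genes are marked.
#'
#' @param decoder_outputs Reconstructed expression (cells x genes), e.g. the
#'   `decoder_output` of a [fit_vae()] or [fit_deconvolution()] object.
#' @param contributions Per-cell contributions or a [fit_hazard()] object.
#' @param top_k Number of genes to mark at each extreme (>= 1).
#' @param cells Optional cell subset (indices, ids, or logical mask).
#' @return A tibble with columns `gene`, `r`, `rank` (descending by `r`),
#'   `selection` (`"top"`, `"bottom"`, or `NA`), and `zero_variance`.
#' @export
gene_contribution_correlation <- function(decoder_outputs, contributions,
                                          top_k = 30, cells = NULL) {
  beta <- resolve_contributions(contributions)
  if (top_k < 1) abort("`top_k` must be at least 1.")
  X <- as.matrix(decoder_outputs)
  if (length(beta) != nrow(X)) {
    abort("`contributions` must have one value per cell (row of `decoder_outputs`).")
  }
  if (!is.null(cells)) {
    if (is.character(cells)) cells <- match(cells, rownames(X))
    X <- X[cells, , drop = FALSE]
    beta <- beta[cells]
  }
  sds <- apply(X, 2, sd)
  zero <- sds == 0 | sd(beta) == 0
  r <- rep(0, ncol(X))
  if (any(!zero)) r[!zero] <- drop(cor(X[, !zero, drop = FALSE], beta))
  out <- tibble::tibble(
    gene = colnames(X) %||% paste0("gene_", seq_len(ncol(X))),
    r = r,
    zero_variance = zero
  )
  out <- dplyr::arrange(out, dplyr::desc(.data$r))
  out$rank <- seq_len(nrow(out))
  k <- min(top_k, nrow(out))
  out$selection <- NA_character_
  out$selection[seq_len(k)] <- "top"
  out$selection[seq(nrow(out) - k + 1, nrow(out))] <- "bottom"
  out
}

# Clip a vector to the [lo, hi] quantiles of `reference` (linear-interpolation
# quantile convention, stats::quantile type 7). The bounds come from the raw
# reference scores -- by default x itself -- so clipping an already-clipped
# copy against the same reference is a projection and therefore idempotent.
clip_quantiles <- function(x, lower = 0.025, upper = 0.975, reference = x) {
  q <- quantile(reference, c(lower, upper), names = FALSE)
  pmin(pmax(x, q[1]), q[2])
}

#' Spatial hazard map
#'
#' Assigns each spot the fraction-weighted sum of per-cell hazard
#' contributions, `score_s = sum_c beta(z_c) * m_spot(z_c)_s`. For display, a
#' clipped copy bounded by the 2.5% and 97.5% quantiles of the raw scores is
#' added; raw scores are retained.
#'
#' @param spot_fit A [fit_spot_deconvolution()] object (or any `deconv_fit`
#'   whose fractions share the hazard fit's cell set).
#' @param contributions Per-cell contributions or a [fit_hazard()] object
#'   fitted on the same frozen reference cells.
#' @return A tibble of class `spatial_hazard_map` with columns `spot_id`,
#'   `x`, `y` (when coordinates are available), `hazard` (raw), and
#'   `hazard_clipped`.
#' @export
spatial_hazard <- function(spot_fit, contributions) {
  stopifnot(inherits(spot_fit, "deconv_fit"))
  beta <- resolve_contributions(contributions)
  if (inherits(contributions, "hazard_fit") &&
    !identical(contributions$cell_id, spot_fit$cell_id)) {
    abort("the hazard fit and the spot fit must share the same reference cells.")
  }
  if (length(beta) != nrow(spot_fit$fractions)) {
    abort("`contributions` must have one value per reference cell.")
  }
  score <- unname(drop(crossprod(spot_fit$fractions, beta)))
  out <- tibble::tibble(
    spot_id = spot_fit$sample_id,
    hazard = score,
    hazard_clipped = clip_quantiles(score)
  )
  if (!is.null(spot_fit$coordinates)) {
    out <- dplyr::left_join(out, spot_fit$coordinates, by = "spot_id")
    out <- out[, c("spot_id", "x", "y", "hazard", "hazard_clipped")]
  }
  class(out) <- c("spatial_hazard_map", class(out))
  out
}

#' Mean spatial hazard per spot group
#'
#' Averages raw (unclipped) spot hazard scores within externally supplied
#' spot groups (e.g. expression-based spatial clusters) and ranks the groups
#' by mean hazard.
#'
#' @param spatial_map A [spatial_hazard()] tibble.
#' @param spot_groups Group label per spot (same order as the map), or a
#'   named vector keyed by `spot_id`.
#' @return A tibble with `group`, `mean_hazard`, `n_spots`, and `rank`
#'   (1 = highest mean hazard).
#' @export
spot_group_mean_hazard <- function(spatial_map, spot_groups) {
  if (!is.null(names(spot_groups))) {
    spot_groups <- spot_groups[spatial_map$spot_id]
  }
  if (length(spot_groups) != nrow(spatial_map) || anyNA(spot_groups)) {
    abort("`spot_groups` must assign a group to every spot.")
  }
  groups <- if (is.factor(spot_groups)) spot_groups else factor(spot_groups)
  if (any(table(groups) == 0)) abort("empty spot group.")
  out <- tibble::tibble(
    group = levels(groups),
    mean_hazard = as.numeric(tapply(spatial_map$hazard, groups, mean)),
    n_spots = as.integer(table(groups))
  )
  out <- dplyr::arrange(out, dplyr::desc(.data$mean_hazard))
  out$rank <- seq_len(nrow(out))
  out
}

#' Cross-dataset similarity of gene-contribution correlations
#'
#' Pairwise Pearson correlation of the per-gene correlation vectors from
#' several [gene_contribution_correlation()] tables, over their shared genes.
#'
#' @param tables A named list (>= 2) of gene-correlation tibbles.
#' @return A symmetric similarity matrix with unit diagonal.
#' @export
cross_dataset_similarity <- function(tables) {
  if (length(tables) < 2) abort("at least two gene-correlation tables are required.")
  genes <- Reduce(intersect, lapply(tables, function(t) t$gene))
  if (length(genes) < 10) abort("fewer than 10 shared genes across tables.")
  mat <- vapply(tables, function(t) t$r[match(genes, t$gene)], numeric(length(genes)))
  colnames(mat) <- names(tables) %||% paste0("dataset_", seq_along(tables))
  cor(mat)
}
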