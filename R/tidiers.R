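# broom-style tidiers and ggplot2 autoplot methods for the fitted objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a VAE fit into per-cell latent coordinates
#'
#' @param x A [fit_vae()] object.
#' @param ... Unused.
#' @return A tibble: `cell_id`, `batch`, `cluster` (if present), and one
#'   column per latent dimension.
#' @export
tidy.vae_fit <- function(x, ...) {
  out <- tibble::tibble(cell_id = x$cell_id, batch = x$batch)
  if (!is.null(x$cluster)) out$cluster <- x$cluster
  dplyr::bind_cols(out, tibble::as_tibble(x$latent_mean))
}

#' @rdname tidy.vae_fit
#' @export
glance.vae_fit <- function(x, ...) {
  tibble::tibble(
    n_cells = length(x$cell_id),
    n_genes = length(x$gene),
    latent_dim = x$latent_dim,
    epochs = nrow(x$history),
    val_elbo = x$best_val_elbo,
    test_loglik = x$test_loglik
  )
}

#' Tidy a deconvolution fit into per-gene parameters
#'
#' @param x A [fit_deconvolution()] object.
#' @param ... Unused.
#' @return The per-gene parameter tibble (`gene`, `capture_rate`, `shift`,
#'   `dispersion`).
#' @export
tidy.deconv_fit <- function(x, ...) x$gene_params

#' @rdname tidy.deconv_fit
#' @export
glance.deconv_fit <- function(x, ...) {
  tibble::tibble(
    type = x$type,
    n_cells = nrow(x$fractions),
    n_samples = ncol(x$fractions),
    n_genes = length(x$gene),
    loglik = utils::tail(x$history$loglik, 1),
    iterations = nrow(x$history)
  )
}

#' Tidy a hazard fit into per-cell contributions
#'
#' @param x A [fit_hazard()] object.
#' @param ... Unused.
#' @return A tibble: `cell_id`, `cluster` (if present), `beta`.
#' @export
tidy.hazard_fit <- function(x, ...) {
  out <- tibble::tibble(cell_id = x$cell_id, beta = unname(x$beta))
  if (!is.null(x$cluster)) {
    out <- dplyr::bind_cols(out[, "cell_id"], tibble::tibble(cluster = x$cluster),
                            out[, "beta"])
  }
  out
}

#' @rdname tidy.hazard_fit
#' @export
glance.hazard_fit <- function(x, ...) {
  tibble::tibble(
    ties = x$ties,
    cindex_train = x$metrics$cindex_train,
    cindex_val = x$metrics$cindex_val,
    cindex_test = x$metrics$cindex_test,
    ibs_test = x$metrics$ibs_test,
    epochs = nrow(x$history)
  )
}

#' Training-curve plot for a VAE fit
#'
#' @param object A [fit_vae()] object.
#' @param ... Unused.
#' @return A ggplot of training and validation objectives per epoch.
#' @export
autoplot.vae_fit <- function(object, ...) {
  long <- tidyr::pivot_longer(object$history, -"epoch",
    names_to = "set", values_to = "elbo"
  )
  ggplot2::ggplot(long, ggplot2::aes(.data$epoch, .data$elbo, colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "ELBO per cell", colour = NULL)
}

#' Log-likelihood trace of a deconvolution fit
#'
#' @param object A [fit_deconvolution()] object.
#' @param ... Unused.
#' @return A ggplot of the NB log-likelihood per iteration.
#' @export
autoplot.deconv_fit <- function(object, ...) {
  ggplot2::ggplot(object$history, ggplot2::aes(.data$iter, .data$loglik)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "iteration", y = "NB log-likelihood")
}

#' Per-cell contribution plot for a hazard fit
#'
#' @param object A [fit_hazard()] object.
#' @param ... Unused.
#' @return A ggplot: contribution distribution per cluster when cluster
#'   labels are available, otherwise a histogram.
#' @export
autoplot.hazard_fit <- function(object, ...) {
  df <- tidy(object)
  if ("cluster" %in% names(df)) {
    ggplot2::ggplot(df, ggplot2::aes(.data$cluster, .data$beta)) +
      ggplot2::geom_boxplot(outlier.size = 0.5) +
      ggplot2::labs(x = NULL, y = "hazard contribution")
  } else {
    ggplot2::ggplot(df, ggplot2::aes(.data$beta)) +
      ggplot2::geom_histogram(bins = 40) +
      ggplot2::labs(x = "hazard contribution", y = "cells")
  }
}

#' Permutation-importance plot
#'
#' @param object A [permutation_importance()] report.
#' @param ... Unused.
#' @return A ggplot of the mean c-index decrement per cluster with +-2 SE
#'   error bars.
#' @export
autoplot.permutation_report <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    stats::reorder(.data$cluster, -.data$decrement), .data$decrement
  )) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbar(
      ggplot2::aes(
        ymin = .data$decrement - 2 * .data$se,
        ymax = .data$decrement + 2 * .data$se
      ),
      width = 0.2
    ) +
    ggplot2::labs(x = NULL, y = "c-index decrement")
}

#' Spatial hazard map plot
#'
#' @param object A [spatial_hazard()] map with coordinates.
#' @param ... Unused.
#' @return A ggplot of spots coloured by the clipped hazard score.
#' @export
autoplot.spatial_hazard_map <- function(object, ...) {
  if (!all(c("x", "y") %in% names(object))) {
    abort("the spatial map carries no coordinates to plot.")
  }
  ggplot2::ggplot(object, ggplot2::aes(.data$x, .data$y, colour = .data$hazard_clipped)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::scale_colour_viridis_c(name = "hazard") +
    ggplot2::coord_equal()
}
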