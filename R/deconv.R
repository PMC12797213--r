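# Stage 2: negative-binomial observation model for bulk samples (or spatial
# spots). The NB mean for gene g in sample b is
#   mu_bg = r_g * sum_c f(z_c, p_c)_g * m(z_c)_b + o_g,
# where f is the frozen Stage-1 decoder, m is a learned cell-fraction map
# (softmax over cells per sample, so fractions sum to 1 over cells), and
# r_g, o_g, alpha_g are positive per-gene capture rate, shift, and
# inverse-dispersion shared across samples.

#' Negative-binomial log-likelihood (mean/dispersion parameterisation)
#'
#' Log-pmf of the negative binomial with mean `mu` and inverse-dispersion
#' `alpha`, i.e. variance `mu + mu^2 / alpha` (`alpha` is the `size` of
#' [stats::dnbinom()]); larger `alpha` approaches the Poisson. Elementwise
#' values are summed.
#'
#' @param observed Non-negative integer observations.
#' @param mean Strictly positive means, recycled against `observed`.
#' @param dispersion Strictly positive inverse-dispersion values.
#' @return Sum of log-pmf values (a scalar `<= 0` for any single observation).
#' @export
nb_loglik <- function(observed, mean, dispersion) {
  if (any(!is.finite(observed)) || any(!is.finite(mean)) || any(!is.finite(dispersion))) {
    abort("`observed`, `mean`, and `dispersion` must be finite.")
  }
  if (any(mean <= 0) || any(dispersion <= 0)) {
    abort("`mean` and `dispersion` must be strictly positive.")
  }
  k <- observed
  a <- dispersion
  mu <- mean
  sum(lgamma(k + a) - lgamma(a) - lgamma(k + 1) +
    a * log(a / (a + mu)) + k * log(mu / (a + mu)))
}

# Column-wise softmax over cells: logits (cells x samples) -> fractions whose
# columns each sum to 1.
softmax_columns <- function(logits) {
  shifted <- sweep(logits, 2, apply(logits, 2, max))
  e <- exp(shifted)
  sweep(e, 2, colSums(e), "/")
}

#' Mixture mean of the bulk observation model
#'
#' `mu_gb = r_g * sum_c f_cg * m_cb + o_g`.
#'
#' @param fractions Cell-fraction matrix (cells x samples), columns summing
#'   to 1.
#' @param decoder_outputs Decoder output matrix (cells x genes).
#' @param r,o Positive per-gene capture rates and shifts (length = genes).
#' @return Mean matrix (genes x samples), strictly positive.
#' @export
bulk_mean <- function(fractions, decoder_outputs, r, o) {
  fractions <- as.matrix(fractions)
  decoder_outputs <- as.matrix(decoder_outputs)
  if (nrow(fractions) != nrow(decoder_outputs)) {
    abort("`fractions` and `decoder_outputs` must have the same number of cells (rows).")
  }
  g <- ncol(decoder_outputs)
  if (length(r) != g || length(o) != g) {
    abort("`r` and `o` must have one entry per gene.")
  }
  if (any(r <= 0) || any(o < 0)) abort("`r` must be positive and `o` non-negative.")
  mu <- r * crossprod(decoder_outputs, fractions) + o
  dimnames(mu) <- list(colnames(decoder_outputs), colnames(fractions))
  mu
}

# Normalise a user-supplied expression matrix: orient samples x genes against
# the reference gene vocabulary, round non-integers with a warning, intersect
# genes.
prepare_expression <- function(x, genes, what = "bulk") {
  if (is.data.frame(x)) {
    id_col <- intersect(c("sample_id", "spot_id"), names(x))
    if (length(id_col)) {
      ids <- as.character(x[[id_col[1]]])
      x <- as.matrix(x[setdiff(names(x), id_col)])
      rownames(x) <- ids
    } else {
      x <- as.matrix(x)
    }
  }
  overlap_cols <- length(intersect(colnames(x), genes))
  overlap_rows <- length(intersect(rownames(x), genes))
  if (overlap_cols == 0 && overlap_rows == 0) {
    abort(sprintf("no %s genes overlap the reference gene vocabulary.", what))
  }
  if (overlap_rows > overlap_cols) {
    inform(sprintf("%s matrix detected as genes x samples; transposing.", what))
    x <- t(x)
  }
  if (any(x < 0)) abort(sprintf("%s expression must be non-negative.", what))
  if (any(x != round(x))) {
    warn(sprintf("non-integer %s expression supplied; rounding for the NB likelihood.", what))
    x <- round(x)
  }
  common <- intersect(genes, colnames(x))
  dropped <- (ncol(x) - length(common)) + (length(genes) - length(common))
  if (dropped > 0) {
    inform(sprintf("gene intersection: %d genes shared, %d dropped.", length(common), dropped))
  }
  if (is.null(rownames(x))) rownames(x) <- paste0("sample_", seq_len(nrow(x)))
  x[, common, drop = FALSE]
}

#' Deconvolve bulk samples against a frozen single-cell reference
#'
#' Maximises the negative-binomial log-likelihood of the bulk expression by
#' Adam over the fraction network (an MLP from latent cell states to
#' per-sample logits, softmaxed across cells) and the per-gene positive
#' parameters (softplus-parameterised capture rate, shift, and
#' inverse-dispersion). Stage-1 parameters are not updated; the latent input
#' is the posterior mean of each cell.
#'
#' @param bulk Expression matrix, samples x genes (genes x samples is
#'   auto-detected via gene-name overlap and transposed), raw counts or
#'   near-counts (non-integers are rounded with a warning).
#' @param vae A fitted [fit_vae()] object (frozen).
#' @param hidden Hidden layer widths of the fraction network.
#' @param lr Adam learning rate.
#' @param max_epochs Maximum full-batch iterations.
#' @param tol Relative log-likelihood improvement per 50 iterations below
#'   which optimisation stops.
#' @param seed Integer seed (network initialisation).
#' @param type `"bulk"` or `"spot"`.
#' @param coordinates Optional tibble (`spot_id`, `x`, `y`) for spot data.
#' @param verbose Print progress.
#' @return An object of class `deconv_fit` with `fractions` (cells x
#'   samples, columns summing to 1), `gene_params` (tibble: gene,
#'   capture_rate, shift, dispersion), `history`, the frozen inputs used
#'   (`latent`, `decoder_output`), and bookkeeping ids.
#' @export
fit_deconvolution <- function(bulk, vae, hidden = c(128, 128), lr = 5e-3,
                              max_epochs = 3000, tol = 1e-6, seed = 1,
                              type = c("bulk", "spot"), coordinates = NULL,
                              verbose = FALSE) {
  stopifnot(inherits(vae, "vae_fit"))
  type <- match.arg(type)
  E <- prepare_expression(bulk, vae$gene, what = type)
  common <- colnames(E)
  Fmat <- vae$decoder_output[, common, drop = FALSE]
  Z <- vae$latent_mean
  K <- t(E) # genes x samples
  B <- ncol(K)
  n_gene <- nrow(K)
  C <- nrow(Z)

  with_seed(seed, {
    net <- mlp_new(ncol(Z), hidden, B)
    fbar <- pmax(colMeans(Fmat), 1e-8)
    ebar <- colMeans(E)
    u_r <- softplus_inv(pmax(ebar, 1e-3) / fbar)
    u_o <- softplus_inv(pmax(0.01 * ebar, 1e-3))
    u_a <- rep(softplus_inv(2), n_gene)
    params <- list(net = mlp_params(net), u_r = u_r, u_o = u_o, u_a = u_a)
    opt <- adam_new(params)

    scale <- B * n_gene
    history <- numeric(max_epochs)
    last_check <- -Inf
    n_iter <- max_epochs
    for (it in seq_len(max_epochs)) {
      net <- mlp_set_params(net, params$net)
      fwd <- mlp_forward(net, Z)
      m <- softmax_columns(fwd$out)
      r <- softplus(params$u_r) + 1e-8
      o <- softplus(params$u_o) + 1e-8
      a <- softplus(params$u_a) + 1e-8
      X <- crossprod(Fmat, m)
      mu <- r * X + o
      ll <- sum(lgamma(K + a) - lgamma(a) - lgamma(K + 1) +
        a * log(a / (a + mu)) + K * log(mu / (a + mu)))
      history[it] <- ll

      d_mu <- K / mu - (K + a) / (a + mu)
      d_a <- rowSums(digamma(K + a) - digamma(a) + log(a / (a + mu)) +
        (mu - K) / (a + mu))
      d_r <- rowSums(d_mu * X)
      d_o <- rowSums(d_mu)
      d_X <- d_mu * r
      d_m <- Fmat %*% d_X
      d_logits <- m * sweep(d_m, 2, colSums(m * d_m))
      back <- mlp_backward(net, fwd, -d_logits / scale)
      grads <- list(
        net = list(W = back$W, b = back$b),
        u_r = -d_r * sigmoid(params$u_r) / scale,
        u_o = -d_o * sigmoid(params$u_o) / scale,
        u_a = -d_a * sigmoid(params$u_a) / scale
      )
      # step decay: full rate for the first half, then 1/3 and 1/10, so the
      # optimiser settles instead of oscillating around the optimum
      lr_it <- lr * if (it <= 0.5 * max_epochs) 1 else if (it <= 0.75 * max_epochs) 1 / 3 else 0.1
      step <- adam_step(params, grads, opt, lr = lr_it)
      params <- step$params
      opt <- step$state

      if (it %% 50 == 0) {
        if (verbose) inform(sprintf("iter %d: loglik %.2f", it, ll))
        if (is.finite(last_check) && (ll - last_check) < tol * abs(last_check)) {
          n_iter <- it
          break
        }
        last_check <- ll
      }
      n_iter <- it
    }

    net <- mlp_set_params(net, params$net)
    m <- softmax_columns(mlp_forward(net, Z)$out)
    dimnames(m) <- list(vae$cell_id, rownames(E))
    structure(
      list(
        fractions = m,
        gene_params = tibble::tibble(
          gene = common,
          capture_rate = softplus(params$u_r) + 1e-8,
          shift = softplus(params$u_o) + 1e-8,
          dispersion = softplus(params$u_a) + 1e-8
        ),
        network = net,
        latent = Z,
        decoder_output = Fmat,
        gene = common,
        cell_id = vae$cell_id,
        cluster = vae$cluster,
        sample_id = rownames(E),
        type = type,
        coordinates = coordinates,
        history = tibble::tibble(iter = seq_len(n_iter), loglik = history[seq_len(n_iter)]),
        vae_decoder_hash = vae$decoder_hash,
        seed = seed
      ),
      class = "deconv_fit"
    )
  })
}

#' @export
print.deconv_fit <- function(x, ...) {
  cat(sprintf(
    "<deconv_fit:%s> %d cells x %d %s, %d genes; final loglik %.2f (%d iterations)\n",
    x$type, nrow(x$fractions), ncol(x$fractions),
    if (x$type == "spot") "spots" else "samples",
    length(x$gene), utils::tail(x$history$loglik, 1), nrow(x$history)
  ))
  invisible(x)
}

#' Deconvolve spatial spots
#'
#' Identical observation model to [fit_deconvolution()], with spots in place
#' of bulk samples and spot-specific per-gene parameters.
#'
#' @param spots Spot expression matrix (spots x genes) or a list with
#'   elements `counts` and `coordinates` as returned by [simulate_spots()].
#' @inheritParams fit_deconvolution
#' @return A `deconv_fit` with `type = "spot"` and spot coordinates attached.
#' @export
fit_spot_deconvolution <- function(spots, vae, coordinates = NULL, ...) {
  if (is.list(spots) && !is.data.frame(spots) && !is.matrix(spots)) {
    coordinates <- coordinates %||% spots$coordinates
    spots <- spots$counts
  }
  fit_deconvolution(spots, vae, type = "spot", coordinates = coordinates, ...)
}

#' Extract the cell-fraction matrix
#'
#' @param fit A [fit_deconvolution()] object.
#' @return Matrix (cells x samples); every column sums to 1.
#' @export
cell_fractions <- function(fit) {
  stopifnot(inherits(fit, "deconv_fit"))
  fit$fractions
}

#' Aggregate cell fractions to cluster proportions
#'
#' @param fractions Cell-fraction matrix (cells x samples) or a `deconv_fit`.
#' @param cluster_labels Per-cell labels covering every cell.
#' @return Matrix (samples x clusters); rows sum to 1.
#' @export
aggregate_fractions <- function(fractions, cluster_labels = NULL) {
  if (inherits(fractions, "deconv_fit")) {
    cluster_labels <- cluster_labels %||% fractions$cluster
    fractions <- fractions$fractions
  }
  if (is.null(cluster_labels)) abort("`cluster_labels` are required.")
  if (length(cluster_labels) != nrow(fractions)) {
    abort("`cluster_labels` must cover every cell (row of `fractions`).")
  }
  if (anyNA(cluster_labels)) abort("unknown (NA) cluster label.")
  agg <- rowsum(fractions, group = as.character(cluster_labels))
  t(agg)
}
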