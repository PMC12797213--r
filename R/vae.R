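# Stage 1: batch-conditional variational autoencoder on raw single-cell
# counts. The prior over the latent state z_c is standard normal, the
# posterior is a diagonal Gaussian produced by the encoder, and counts are
# Poisson with rate l_c * f(z_c, p_c), where l_c is the per-cell mean count
# over genes and f is the decoder with a softplus output head.

#' Poisson log-likelihood
#'
#' @param x Observed counts (non-negative).
#' @param rate Poisson rates (strictly positive), same shape as `x`.
#' @return Sum of elementwise Poisson log-pmf values.
#' @export
poisson_loglik <- function(x, rate) {
  if (any(rate <= 0)) abort("`rate` must be strictly positive.")
  sum(x * log(rate) - rate - lgamma(x + 1))
}

#' KL divergence of a diagonal Gaussian from the standard normal
#'
#' Closed form of `KL(N(mu, diag(sd^2)) || N(0, I))`, summed over all
#' coordinates supplied.
#'
#' @param mu,sd Posterior means and standard deviations (`sd > 0`).
#' @return A non-negative scalar.
#' @export
kl_standard_normal <- function(mu, sd) {
  if (any(sd <= 0)) abort("`sd` must be strictly positive.")
  sum(0.5 * (mu^2 + sd^2 - 1) - log(sd))
}

# Encoder input representation: log1p counts next to the batch one-hot.
vae_input <- function(counts, onehot) cbind(log1p(counts), onehot)

# Full forward pass through encoder head: means and log-sds (clamped).
encoder_pass <- function(encoder, counts, onehot, latent_dim) {
  fwd <- mlp_forward(encoder, vae_input(counts, onehot))
  mu <- fwd$out[, seq_len(latent_dim), drop = FALSE]
  s_raw <- fwd$out[, latent_dim + seq_len(latent_dim), drop = FALSE]
  s <- pmin(pmax(s_raw, -7), 7)
  list(fwd = fwd, mu = mu, s = s, sd = exp(s), mask = (s_raw > -7 & s_raw < 7))
}

decoder_pass <- function(decoder, z, onehot, rate_floor) {
  fwd <- mlp_forward(decoder, cbind(z, onehot))
  f <- softplus(fwd$out) + rate_floor
  list(fwd = fwd, f = f)
}

#' Fit the conditional VAE on a single-cell reference
#'
#' Cells are split at random into training/validation/test sets (default
#' 85/10/5); training minimises the negative evidence lower bound (Poisson
#' reconstruction log-likelihood minus the KL of the posterior from the
#' standard-normal prior) by Adam on minibatches, with early stopping on the
#' validation objective. After training, parameters are frozen and the
#' posterior (mean, sd), a seeded posterior sample, and the decoder output at
#' the posterior mean are returned for every cell.
#'
#' @param reference A [cell_reference()].
#' @param latent_dim Latent dimension M (default 10).
#' @param hidden Hidden layer widths of encoder and decoder MLPs.
#' @param lr Adam learning rate.
#' @param batch_size Minibatch size.
#' @param max_epochs Maximum training epochs.
#' @param patience Early-stopping patience in epochs without validation
#'   improvement.
#' @param split Cell split fractions (train, validation, test), summing to 1.
#' @param rate_floor Small constant added to the decoder rate to avoid
#'   `log(0)`.
#' @param seed Integer seed covering the split, initialisation, minibatch
#'   order, and reparameterisation noise.
#' @param verbose Print per-epoch objectives.
#' @return An object of class `vae_fit` carrying the frozen encoder/decoder,
#'   per-cell posterior summaries (`latent_mean`, `latent_sd`,
#'   `latent_sample`), the decoder output at the posterior mean
#'   (`decoder_output`), a training `history` tibble, and the held-out test
#'   reconstruction log-likelihood per cell (`test_loglik`).
#' @export
fit_vae <- function(reference, latent_dim = 10, hidden = c(128, 128),
                    lr = 1e-3, batch_size = 128, max_epochs = 400,
                    patience = 20, split = c(0.85, 0.10, 0.05),
                    rate_floor = 1e-8, seed = 1, verbose = FALSE) {
  if (!inherits(reference, "cell_reference")) abort("`reference` must be a cell_reference.")
  if (abs(sum(split) - 1) > 1e-9) abort("`split` fractions must sum to 1.")
  counts <- reference$counts
  onehot <- batch_onehot(reference)
  l <- reference$library_mean
  n <- nrow(counts)
  G <- ncol(counts)
  P <- ncol(onehot)

  with_seed(seed, {
    idx <- sample.int(n)
    n_tr <- floor(split[1] * n)
    n_va <- floor(split[2] * n)
    if (n_tr < 1 || n_va < 1 || n - n_tr - n_va < 1) {
      abort("too few cells for a train/validation/test split.")
    }
    tr <- idx[seq_len(n_tr)]
    va <- idx[n_tr + seq_len(n_va)]
    te <- idx[(n_tr + n_va + 1):n]

    encoder <- mlp_new(G + P, hidden, 2L * latent_dim)
    decoder <- mlp_new(latent_dim + P, rev(hidden), G)
    params <- list(enc = mlp_params(encoder), dec = mlp_params(decoder))
    opt <- adam_new(params)

    # Deterministic per-cell objective at the posterior mean (KL kept exact);
    # used for early stopping and reporting.
    eval_objective <- function(cells) {
      enc <- encoder_pass(encoder, counts[cells, , drop = FALSE],
                          onehot[cells, , drop = FALSE], latent_dim)
      dec <- decoder_pass(decoder, enc$mu, onehot[cells, , drop = FALSE], rate_floor)
      rate <- dec$f * l[cells]
      rec <- poisson_loglik(counts[cells, , drop = FALSE], rate)
      kl <- kl_standard_normal(enc$mu, enc$sd)
      (rec - kl) / length(cells)
    }

    history <- vector("list", max_epochs)
    best_val <- -Inf
    best_params <- params
    wait <- 0L
    for (epoch in seq_len(max_epochs)) {
      encoder <- mlp_set_params(encoder, params$enc)
      decoder <- mlp_set_params(decoder, params$dec)
      order_tr <- sample(tr)
      starts <- seq(1, length(order_tr), by = batch_size)
      elbo_sum <- 0
      for (st in starts) {
        cells <- order_tr[st:min(st + batch_size - 1L, length(order_tr))]
        nb <- length(cells)
        x <- counts[cells, , drop = FALSE]
        oh <- onehot[cells, , drop = FALSE]
        lb <- l[cells]

        enc <- encoder_pass(encoder, x, oh, latent_dim)
        eps <- matrix(rnorm(nb * latent_dim), nb, latent_dim)
        z <- enc$mu + enc$sd * eps
        dec <- decoder_pass(decoder, z, oh, rate_floor)
        rate <- dec$f * lb

        rec <- poisson_loglik(x, rate)
        kl <- kl_standard_normal(enc$mu, enc$sd)
        elbo_sum <- elbo_sum + (rec - kl)

        # Backward pass of the scaled negative ELBO.
        d_rate <- -(x / rate - 1) / nb
        d_f <- d_rate * lb
        d_pre <- d_f * sigmoid(dec$fwd$out)
        back_dec <- mlp_backward(decoder, dec$fwd, d_pre)
        d_z <- back_dec$d_input[, seq_len(latent_dim), drop = FALSE]
        d_mu <- d_z + enc$mu / nb
        d_s <- (d_z * eps * enc$sd + (enc$sd^2 - 1) / nb) * enc$mask
        back_enc <- mlp_backward(encoder, enc$fwd, cbind(d_mu, d_s))

        step <- adam_step(
          params,
          list(enc = list(W = back_enc$W, b = back_enc$b),
               dec = list(W = back_dec$W, b = back_dec$b)),
          opt, lr = lr
        )
        params <- step$params
        opt <- step$state
        encoder <- mlp_set_params(encoder, params$enc)
        decoder <- mlp_set_params(decoder, params$dec)
      }
      val <- eval_objective(va)
      history[[epoch]] <- tibble::tibble(
        epoch = epoch,
        train_elbo = elbo_sum / length(tr),
        val_elbo = val
      )
      if (verbose) {
        inform(sprintf("epoch %d: train %.4f  val %.4f", epoch,
                       elbo_sum / length(tr), val))
      }
      if (val > best_val) {
        best_val <- val
        best_params <- params
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= patience) break
      }
    }
    params <- best_params
    encoder <- mlp_set_params(encoder, params$enc)
    decoder <- mlp_set_params(decoder, params$dec)

    enc_all <- encoder_pass(encoder, counts, onehot, latent_dim)
    eps_all <- matrix(rnorm(n * latent_dim), n, latent_dim)
    z_sample <- enc_all$mu + enc_all$sd * eps_all
    dec_all <- decoder_pass(decoder, enc_all$mu, onehot, rate_floor)
    dimnames(enc_all$mu) <- list(reference$cell_id, paste0("z", seq_len(latent_dim)))
    dimnames(dec_all$f) <- list(reference$cell_id, reference$gene)

    test_rate <- dec_all$f[te, , drop = FALSE] * l[te]
    test_loglik <- poisson_loglik(counts[te, , drop = FALSE], test_rate) / length(te)

    structure(
      list(
        encoder = encoder,
        decoder = decoder,
        latent_dim = latent_dim,
        rate_floor = rate_floor,
        batch_levels = levels(reference$batch),
        gene = reference$gene,
        cell_id = reference$cell_id,
        batch = reference$batch,
        cluster = reference$cluster,
        library_mean = l,
        latent_mean = enc_all$mu,
        latent_sd = structure(enc_all$sd, dimnames = dimnames(enc_all$mu)),
        latent_sample = structure(z_sample, dimnames = dimnames(enc_all$mu)),
        decoder_output = dec_all$f,
        split = list(train = reference$cell_id[tr], validation = reference$cell_id[va],
                     test = reference$cell_id[te]),
        history = dplyr::bind_rows(history),
        best_val_elbo = best_val,
        test_loglik = test_loglik,
        seed = seed,
        decoder_hash = hash(params$dec)
      ),
      class = "vae_fit"
    )
  })
}

#' @export
print.vae_fit <- function(x, ...) {
  cat(sprintf(
    "<vae_fit> %d cells x %d genes -> %d latent dims; %d epochs, val ELBO %.4f, test loglik/cell %.4f\n",
    length(x$cell_id), length(x$gene), x$latent_dim, nrow(x$history),
    x$best_val_elbo, x$test_loglik
  ))
  invisible(x)
}

#' Encode cells into the latent posterior
#'
#' @param vae A fitted [fit_vae()] object.
#' @param reference A [cell_reference()] over the same genes and batch levels.
#' @param sample If `TRUE`, also draw a reparameterised posterior sample
#'   `z = mu + sd * eps`.
#' @param seed Seed for the sample.
#' @return A list with `mean` and `sd` matrices (cells x latent dims) and,
#'   when `sample = TRUE`, `sample`.
#' @export
encode_cells <- function(vae, reference, sample = FALSE, seed = 1) {
  stopifnot(inherits(vae, "vae_fit"), inherits(reference, "cell_reference"))
  if (!identical(reference$gene, vae$gene)) {
    abort("`reference` genes must match the genes the VAE was trained on.")
  }
  if (!all(levels(reference$batch) %in% vae$batch_levels)) {
    abort("`reference` contains batch levels unseen in training.")
  }
  oh <- matrix(0, nrow(reference$counts), length(vae$batch_levels),
    dimnames = list(reference$cell_id, vae$batch_levels)
  )
  oh[cbind(seq_along(reference$batch),
           match(as.character(reference$batch), vae$batch_levels))] <- 1
  enc <- encoder_pass(vae$encoder, reference$counts, oh, vae$latent_dim)
  out <- list(mean = enc$mu, sd = enc$sd)
  if (sample) {
    out$sample <- with_seed(seed, {
      enc$mu + enc$sd * matrix(rnorm(length(enc$mu)), nrow(enc$mu), ncol(enc$mu))
    })
  }
  out
}

#' Decode latent states into normalised expression
#'
#' Returns the strictly positive decoder output `f(z, p)`; the Poisson
#' reconstruction mean for a cell is `library_mean * f(z, p)`.
#'
#' @param vae A fitted [fit_vae()] object.
#' @param z Latent matrix (cells x latent dims).
#' @param batch Batch labels (one per row of `z`), matching training levels.
#' @return A positive matrix (cells x genes).
#' @export
decode_cells <- function(vae, z, batch) {
  stopifnot(inherits(vae, "vae_fit"))
  z <- as.matrix(z)
  if (ncol(z) != vae$latent_dim) {
    abort(sprintf("`z` must have %d columns (the latent dimension).", vae$latent_dim))
  }
  batch <- as.character(batch)
  if (length(batch) != nrow(z)) abort("`batch` must have one label per row of `z`.")
  if (!all(batch %in% vae$batch_levels)) abort("unknown batch level in `batch`.")
  oh <- matrix(0, nrow(z), length(vae$batch_levels))
  oh[cbind(seq_len(nrow(z)), match(batch, vae$batch_levels))] <- 1
  f <- decoder_pass(vae$decoder, z, oh, vae$rate_floor)$f
  colnames(f) <- vae$gene
  f
}

#' Evidence lower bound of a fitted VAE on a set of cells
#'
#' Draws one reparameterised posterior sample per cell and returns the ELBO
#' `sum_c [log Poisson(x_c | l_c f(z_c, p_c)) - KL(q_c || N(0, I))]`, with the
#' reconstruction and KL parts attached as attributes.
#'
#' @inheritParams encode_cells
#' @param cells Optional subset of cells (indices or ids).
#' @param seed Seed for the posterior sample.
#' @return The scalar ELBO with attributes `"reconstruction"` and `"kl"`.
#' @export
vae_elbo <- function(vae, reference, cells = NULL, seed = 1) {
  if (!is.null(cells)) reference <- reference[cells]
  if (nrow(reference$counts) == 0) abort("empty batch of cells.")
  post <- encode_cells(vae, reference, sample = TRUE, seed = seed)
  f <- decode_cells(vae, post$sample, reference$batch)
  rate <- f * reference$library_mean
  rec <- poisson_loglik(reference$counts, rate)
  kl <- kl_standard_normal(post$mean, post$sd)
  structure(rec - kl, reconstruction = rec, kl = kl)
}
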