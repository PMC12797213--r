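# Stage 3: learn per-cell hazard contributions beta(z_c). The per-sample
# linear predictor is eta_b = sum_c beta(z_c) * m(z_c)_b with the Stage-2
# fractions m frozen; the beta network is trained by maximising the Cox
# partial log-likelihood (Breslow or Efron) on a training split of the bulk
# samples, with early stopping on the validation partial likelihood.

#' Fit per-cell hazard contributions
#'
#' @param deconv A frozen [fit_deconvolution()] object (carries the latent
#'   states and the cell-fraction matrix).
#' @param survival A [survival_table()] covering every deconvolved sample.
#' @param ties Tie handling for the partial likelihood: `"auto"` (Efron when
#'   tied event times exist, Breslow otherwise), `"efron"`, or `"breslow"`.
#' @param split Sample split fractions (train, validation, test).
#' @param hidden Hidden layer widths of the contribution network
#'   (latent state to scalar, linear output so contributions are signed).
#' @param lr Adam learning rate.
#' @param max_epochs Maximum full-batch epochs.
#' @param patience Early-stopping patience (epochs without validation
#'   improvement).
#' @param seed Integer seed (split and initialisation).
#' @param verbose Print progress.
#' @return An object of class `hazard_fit` with per-cell `beta`, per-sample
#'   `eta`, the data splits, a `metrics` list (train/validation/test
#'   concordance, test integrated Brier score), and a training `history`.
#' @export
fit_hazard <- function(deconv, survival, ties = c("auto", "efron", "breslow"),
                       split = c(0.6, 0.2, 0.2), hidden = c(64, 64), lr = 1e-3,
                       max_epochs = 2000, patience = 20, seed = 1,
                       verbose = FALSE) {
  stopifnot(inherits(deconv, "deconv_fit"))
  if (!inherits(survival, "survival_table")) survival <- survival_table(survival)
  if (abs(sum(split) - 1) > 1e-9) abort("`split` fractions must sum to 1.")
  miss <- setdiff(deconv$sample_id, survival$sample_id)
  if (length(miss)) {
    abort(sprintf("survival table is missing sample(s): %s ...", miss[1]))
  }
  survival <- survival[match(deconv$sample_id, survival$sample_id), ]
  m <- deconv$fractions
  Z <- deconv$latent
  B <- ncol(m)

  with_seed(seed, {
    idx <- sample.int(B)
    n_tr <- floor(split[1] * B)
    n_va <- floor(split[2] * B)
    if (n_tr < 2 || n_va < 1 || B - n_tr - n_va < 1) {
      abort("too few samples for a train/validation/test split.")
    }
    tr <- idx[seq_len(n_tr)]
    va <- idx[n_tr + seq_len(n_va)]
    te <- idx[(n_tr + n_va + 1):B]
    surv_tr <- survival[tr, ]
    surv_va <- survival[va, ]
    surv_te <- survival[te, ]
    if (sum(surv_tr$event) == 0) abort("training split contains zero events.")
    ties_used <- resolve_ties(ties, surv_tr)
    ll_fun <- if (ties_used == "efron") efron_loglik else breslow_loglik

    net <- mlp_new(ncol(Z), hidden, 1L)
    params <- mlp_params(net)
    opt <- adam_new(params)
    m_tr <- m[, tr, drop = FALSE]
    n_ev <- sum(surv_tr$event)

    history <- vector("list", max_epochs)
    best_val <- -Inf
    best_params <- params
    wait <- 0L
    for (epoch in seq_len(max_epochs)) {
      net <- mlp_set_params(net, params)
      fwd <- mlp_forward(net, Z)
      beta <- drop(fwd$out)
      eta <- drop(crossprod(m, beta))
      ll_tr <- ll_fun(eta[tr], surv_tr)
      d_eta <- cox_grad(eta[tr], surv_tr, ties_used)
      d_beta <- drop(m_tr %*% d_eta)
      back <- mlp_backward(net, fwd, matrix(-d_beta / n_ev, ncol = 1))
      step <- adam_step(params, list(W = back$W, b = back$b), opt, lr = lr)
      params <- step$params
      opt <- step$state

      ll_va <- ll_fun(eta[va], surv_va)
      history[[epoch]] <- tibble::tibble(
        epoch = epoch, train_loglik = ll_tr, val_loglik = ll_va
      )
      if (verbose && epoch %% 100 == 0) {
        inform(sprintf("epoch %d: train %.3f val %.3f", epoch, ll_tr, ll_va))
      }
      if (ll_va > best_val) {
        best_val <- ll_va
        best_params <- params
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= patience) break
      }
    }
    net <- mlp_set_params(net, best_params)
    beta <- drop(mlp_forward(net, Z)$out)
    names(beta) <- deconv$cell_id
    eta <- drop(crossprod(m, beta))
    names(eta) <- deconv$sample_id

    baseline <- breslow_baseline(eta[tr], surv_tr)
    ibs_test <- tryCatch(
      integrated_brier_score(eta[te], surv_te, baseline = baseline),
      error = function(e) {
        warn(paste("test IBS unavailable:", conditionMessage(e)))
        NA_real_
      }
    )
    metrics <- list(
      cindex_train = concordance_index(eta[tr], surv_tr),
      cindex_val = concordance_index(eta[va], surv_va),
      cindex_test = concordance_index(eta[te], surv_te),
      cindex_full = concordance_index(eta, survival),
      ibs_test = ibs_test,
      val_loglik = best_val
    )
    structure(
      list(
        beta = beta,
        eta = eta,
        network = net,
        ties = ties_used,
        split = list(
          train = deconv$sample_id[tr],
          validation = deconv$sample_id[va],
          test = deconv$sample_id[te]
        ),
        metrics = metrics,
        history = dplyr::bind_rows(history),
        baseline = baseline,
        survival = survival,
        cluster = deconv$cluster,
        cell_id = deconv$cell_id,
        sample_id = deconv$sample_id,
        fractions_hash = hash(deconv$fractions),
        seed = seed
      ),
      class = "hazard_fit"
    )
  })
}

#' @export
print.hazard_fit <- function(x, ...) {
  cat(sprintf(
    "<hazard_fit> %d cells, %d samples (%s ties); c-index train %.3f / val %.3f / test %.3f\n",
    length(x$beta), length(x$eta), x$ties,
    x$metrics$cindex_train, x$metrics$cindex_val, x$metrics$cindex_test
  ))
  invisible(x)
}

#' Split-resampled confidence interval for the test concordance index
#'
#' Refits the hazard stage under independent train/validation/test splits of
#' the bulk samples (Stages 1-2 stay frozen) and returns a percentile
#' confidence interval of the test c-index.
#'
#' @inheritParams fit_hazard
#' @param n_iter Number of independent splits (>= 2).
#' @param level Confidence level (default 0.95).
#' @param ... Passed to [fit_hazard()].
#' @return A list with `lower`, `upper`, and a tibble `cindex` of per-split
#'   test c-indices.
#' @export
resample_cindex_ci <- function(deconv, survival, n_iter = 20, seed = 1,
                               level = 0.95, ...) {
  if (n_iter < 2) abort("`n_iter` must be at least 2.")
  cidx <- vapply(seq_len(n_iter), function(i) {
    fit <- fit_hazard(deconv, survival, seed = derive_seed(seed, i), ...)
    fit$metrics$cindex_test
  }, numeric(1))
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  ci <- quantile(cidx, probs, names = FALSE)
  list(
    lower = ci[1],
    upper = ci[2],
    cindex = tibble::tibble(iteration = seq_len(n_iter), cindex_test = cidx)
  )
}
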