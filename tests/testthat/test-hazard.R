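test_that("partial log-likelihoods reproduce hand-computed values", {
  st3 <- survival_table(data.frame(sample_id = c("a", "b", "c"), time = 1:3, event = 1))
  expect_equal(breslow_loglik(c(0, 0, 0), st3), -(log(3) + log(2)), tolerance = 1e-12)

  st2 <- survival_table(data.frame(sample_id = c("a", "b"), time = c(1, 2), event = 1))
  expect_equal(breslow_loglik(c(log(2), 0), st2), log(2) - log(3), tolerance = 1e-12)

  tied <- survival_table(data.frame(sample_id = c("a", "b"), time = c(1, 1), event = 1))
  expect_equal(breslow_loglik(c(0, 0), tied), -2 * log(2), tolerance = 1e-12)
  expect_equal(efron_loglik(c(0, 0), tied), -(log(2) + log(1)), tolerance = 1e-12)

  expect_error(
    breslow_loglik(c(0, 0), survival_table(
      data.frame(sample_id = c("a", "b"), time = c(1, 2), event = 0)
    )),
    "without any events"
  )
})

test_that("Breslow and Efron agree with the survival package on random tied data", {
  for (i in 1:50) {
    st <- random_tied_survival(30, seed = 100 + i)
    if (sum(st$event) == 0) next
    eta <- cellhazard:::with_seed(200 + i, rnorm(30))
    expect_equal(breslow_loglik(eta, st), coxph_loglik_at(eta, st, "breslow"),
      tolerance = 1e-6
    )
    expect_equal(efron_loglik(eta, st), coxph_loglik_at(eta, st, "efron"),
      tolerance = 1e-6
    )
  }
  # tie-free data: the two likelihoods coincide
  cellhazard:::with_seed(5, {
    st <- survival_table(tibble::tibble(
      sample_id = paste0("s", 1:40),
      time = runif(40, 1, 10),
      event = rbinom(40, 1, 0.7)
    ))
    eta <- rnorm(40)
    expect_equal(efron_loglik(eta, st), breslow_loglik(eta, st), tolerance = 1e-12)
  })
})

test_that("analytic likelihood gradients match central finite differences", {
  for (ties in c("breslow", "efron")) {
    st <- random_tied_survival(25, seed = 7)
    eta <- cellhazard:::with_seed(8, rnorm(25))
    ll_fun <- if (ties == "efron") efron_loglik else breslow_loglik
    g <- cellhazard:::cox_grad(eta, st, ties)
    h <- 1e-5
    for (j in sample(25, 8)) {
      up <- eta; up[j] <- up[j] + h
      dn <- eta; dn[j] <- dn[j] - h
      fd <- (ll_fun(up, st) - ll_fun(dn, st)) / (2 * h)
      expect_equal(g[j], fd, tolerance = 1e-4)
    }
  }
})

test_that("partial likelihood is invariant to constant shifts of eta", {
  st <- random_tied_survival(30, seed = 9)
  eta <- cellhazard:::with_seed(10, rnorm(30))
  expect_equal(breslow_loglik(eta + 17.3, st), breslow_loglik(eta, st), tolerance = 1e-9)
  expect_equal(efron_loglik(eta - 5.1, st), efron_loglik(eta, st), tolerance = 1e-9)
})

test_that("maximising our partial likelihood recovers the coxph coefficient", {
  cellhazard:::with_seed(11, {
    x <- rnorm(300)
    u <- runif(300)
    time <- -log(u) / exp(0.8 * x)
    st <- survival_table(tibble::tibble(
      sample_id = paste0("s", 1:300), time = time, event = 1L
    ))
    ours <- optimize(function(b) breslow_loglik(b * x, st), c(-5, 5), maximum = TRUE)$maximum
    oracle <- unname(coef(survival::coxph(survival::Surv(time, st$event) ~ x, ties = "breslow")))
    expect_lt(abs(ours - oracle), 1e-4)
  })
})

test_that("the concordance index behaves per Harrell", {
  st <- survival_table(data.frame(sample_id = c("a", "b", "c"), time = 1:3, event = 1))
  expect_equal(concordance_index(c(3, 2, 1), st), 1.0)
  expect_equal(concordance_index(c(1, 1, 1), st), 0.5)
  expect_error(
    concordance_index(c(1, 2), survival_table(
      data.frame(sample_id = c("a", "b"), time = c(1, 2), event = 0)
    )),
    "comparable"
  )

  # invariant under strictly monotone transforms of eta
  st2 <- random_tied_survival(40, seed = 12)
  eta <- cellhazard:::with_seed(13, rnorm(40))
  expect_identical(
    concordance_index(eta, st2),
    concordance_index(exp(2 * eta) + 3, st2)
  )

  # permutation of sample order changes nothing
  perm <- cellhazard:::with_seed(14, sample(40))
  expect_identical(concordance_index(eta[perm], st2[perm, ]), concordance_index(eta, st2))

  # agrees with the survival package on tie-free data
  cellhazard:::with_seed(15, {
    time <- runif(60, 1, 10)
    event <- rbinom(60, 1, 0.7)
    event[1] <- 1L
    eta2 <- rnorm(60)
    st3 <- survival_table(tibble::tibble(
      sample_id = paste0("s", 1:60), time = time, event = event
    ))
    oracle <- survival::concordance(survival::Surv(time, event) ~ eta2, reverse = TRUE)$concordance
    expect_equal(concordance_index(eta2, st3), oracle, tolerance = 1e-12)
  })
})

test_that("a random predictor has null concordance 0.5", {
  cs <- cellhazard:::with_seed(16, {
    vapply(seq_len(1000), function(i) {
      time <- runif(200, 1, 10)
      event <- rbinom(200, 1, 0.7)
      if (sum(event) == 0) event[1] <- 1L
      st <- survival_table(tibble::tibble(
        sample_id = paste0("s", 1:200), time = time, event = event
      ))
      concordance_index(rnorm(200), st)
    }, numeric(1))
  })
  expect_lt(abs(mean(cs) - 0.5), 0.02)
})

test_that("the integrated Brier score matches closed forms and a naive oracle", {
  # constant predicted survival 1/2 and no censoring: Brier(t) = 1/4 everywhere
  cellhazard:::with_seed(17, {
    time <- runif(50, 1, 10)
    st <- survival_table(tibble::tibble(
      sample_id = paste0("s", 1:50), time = time, event = 1L
    ))
    flat <- tibble::tibble(time = 1e-9, hazard = log(2), cumhaz = log(2))
    expect_equal(
      integrated_brier_score(rep(0, 50), st, baseline = flat),
      0.25,
      tolerance = 1e-12
    )
  })

  # naive per-definition reimplementation as oracle on random censored data
  naive_ibs <- function(eta, st, baseline, grid) {
    sf <- survival::survfit(survival::Surv(st$time, 1 - st$event) ~ 1)
    G <- function(t) c(1, sf$surv)[findInterval(t, sf$time) + 1]
    Gm <- function(t) c(1, sf$surv)[findInterval(t, sf$time, left.open = TRUE) + 1]
    H <- function(t) {
      out <- 0
      for (j in seq_along(baseline$time)) if (baseline$time[j] <= t) out <- baseline$cumhaz[j]
      out
    }
    bs <- sapply(grid, function(t) {
      tot <- 0
      for (b in seq_len(nrow(st))) {
        s <- exp(-H(t) * exp(eta[b]))
        if (st$time[b] <= t && st$event[b] == 1) {
          tot <- tot + (0 - s)^2 / Gm(st$time[b])
        } else if (st$time[b] > t) {
          tot <- tot + (1 - s)^2 / G(t)
        }
      }
      tot / nrow(st)
    })
    sum((bs[-1] + bs[-length(bs)]) / 2 * diff(grid)) / diff(range(grid))
  }
  for (i in 1:5) {
    st <- cellhazard:::with_seed(20 + i, {
      survival_table(tibble::tibble(
        sample_id = paste0("s", 1:60),
        time = runif(60, 1, 10),
        event = rbinom(60, 1, 0.7)
      ))
    })
    eta <- cellhazard:::with_seed(30 + i, rnorm(60, sd = 0.5))
    bl <- breslow_baseline(eta, st)
    grid <- seq(min(st$time), quantile(st$time, 0.8), length.out = 40)
    expect_equal(
      integrated_brier_score(eta, st, baseline = bl, time_grid = grid),
      naive_ibs(eta, st, bl, grid),
      tolerance = 1e-6
    )
  }
})

test_that("fit_hazard freezes fractions, splits samples, and reports metrics", {
  fx <- tiny_fixture()
  frac_hash <- rlang::hash(fx$deconv$fractions)
  fit <- fit_hazard(fx$deconv, fx$survival, max_epochs = 300, seed = 40)
  expect_identical(rlang::hash(fx$deconv$fractions), frac_hash)
  expect_identical(fit$fractions_hash, frac_hash)

  expect_length(fit$beta, nrow(fx$deconv$fractions))
  expect_length(fit$eta, ncol(fx$deconv$fractions))
  expect_setequal(
    c(fit$split$train, fit$split$validation, fit$split$test),
    fx$deconv$sample_id
  )
  expect_true(fit$metrics$cindex_test >= 0 && fit$metrics$cindex_test <= 1)

  # eta is the fraction-weighted sum of per-cell contributions
  expect_equal(
    unname(fit$eta),
    unname(drop(crossprod(fx$deconv$fractions, fit$beta))),
    tolerance = 1e-12
  )

  # adding a constant to all contributions leaves the partial likelihood
  # unchanged because fractions sum to one per sample
  eta_shift <- drop(crossprod(fx$deconv$fractions, fit$beta + 4.2))
  expect_equal(
    breslow_loglik(eta_shift, fit$survival),
    breslow_loglik(fit$eta, fit$survival),
    tolerance = 1e-9
  )

  all_censored <- fx$survival
  all_censored$event <- 0L
  expect_error(fit_hazard(fx$deconv, all_censored, seed = 40), "zero events")
})

test_that("split-resampled c-index CI is ordered and covers its draws", {
  fx <- tiny_fixture()
  ci <- resample_cindex_ci(fx$deconv, fx$survival,
    n_iter = 4, seed = 41, max_epochs = 150
  )
  expect_lte(ci$lower, ci$upper)
  expect_gte(ci$lower, min(ci$cindex$cindex_test))
  expect_lte(ci$upper, max(ci$cindex$cindex_test))
  expect_identical(nrow(ci$cindex), 4L)
  expect_error(resample_cindex_ci(fx$deconv, fx$survival, n_iter = 1), "n_iter")
})
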