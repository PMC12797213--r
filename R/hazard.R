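# Extended Cox model machinery: partial log-likelihoods with Breslow/Efron tie
# handling (values and analytic gradients), concordance index, Breslow baseline
# hazard and IPCW integrated Brier score.

#' Construct a survival table
#'
#' @param data A data frame with columns `sample_id`, `time` (positive), and
#'   `event` (0 = censored, 1 = event).
#' @return A tibble of class `survival_table`.
#' @examples
#' survival_table(data.frame(sample_id = c("a", "b"), time = c(2, 5),
#'                           event = c(1, 0)))
#' @export
survival_table <- function(data) {
  data <- tibble::as_tibble(data)
  need <- c("sample_id", "time", "event")
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    abort(sprintf("survival table is missing column(s): %s", paste(miss, collapse = ", ")))
  }
  if (!is.numeric(data$time) || any(!is.finite(data$time)) || any(data$time <= 0)) {
    abort("`time` must be positive and finite.")
  }
  if (!all(data$event %in% c(0, 1))) abort("`event` must be 0 or 1.")
  if (anyDuplicated(data$sample_id)) abort("`sample_id` must be unique.")
  data$event <- as.integer(data$event)
  class(data) <- c("survival_table", class(data))
  data
}

# Sorted-order bookkeeping shared by the likelihoods: positions sorted by time,
# tie groups of identical times, first risk-set index and event count per group.
cox_prep <- function(survival) {
  ord <- order(survival$time)
  time_s <- survival$time[ord]
  event_s <- survival$event[ord]
  grp <- match(time_s, unique(time_s))
  first <- match(unique(grp), grp)
  d <- as.integer(tapply(event_s, grp, sum))
  list(ord = ord, time = time_s, event = event_s, grp = grp, first = first, d = d)
}

check_eta <- function(eta, survival) {
  if (length(eta) != nrow(survival)) {
    abort("`eta` must have one value per sample in the survival table.")
  }
  if (any(!is.finite(eta))) abort("`eta` must be finite.")
  if (sum(survival$event) == 0) {
    abort("partial likelihood is undefined without any events.")
  }
  invisible(TRUE)
}

#' Cox partial log-likelihood of a fixed linear predictor
#'
#' `breslow_loglik()` computes
#' \deqn{\sum_{b: I_b = 1} \big(\eta_b - \log \sum_{i: T_i \ge T_b} e^{\eta_i}\big),}
#' the Breslow partial log-likelihood. `efron_loglik()` applies the Efron tie
#' correction: within a group of `d` tied events, the `r`-th term subtracts
#' `((r-1)/d)` times the tied-event contribution from the risk-set sum before
#' taking the log. Both coincide when no event times are tied. Computations
#' are log-sum-exp stabilised and invariant to adding a constant to `eta`.
#'
#' @param eta Numeric linear predictor, one value per sample.
#' @param survival A [survival_table()].
#' @return A scalar partial log-likelihood.
#' @examples
#' st <- survival_table(data.frame(sample_id = letters[1:3], time = 1:3,
#'                                 event = 1))
#' breslow_loglik(c(0, 0, 0), st)  # -(log 3 + log 2)
#' @export
breslow_loglik <- function(eta, survival) {
  check_eta(eta, survival)
  p <- cox_prep(survival)
  et <- eta - max(eta)
  es <- exp(et[p$ord])
  risk <- rev(cumsum(rev(es)))[p$first]
  sum(et[p$ord][p$event == 1]) - sum(p$d * log(risk))
}

#' @rdname breslow_loglik
#' @export
efron_loglik <- function(eta, survival) {
  check_eta(eta, survival)
  p <- cox_prep(survival)
  et <- eta - max(eta)
  es <- exp(et[p$ord])
  risk <- rev(cumsum(rev(es)))[p$first]
  ll <- sum(et[p$ord][p$event == 1])
  for (g in seq_along(p$first)) {
    d <- p$d[g]
    if (d == 0) next
    tied <- sum(es[p$grp == g & p$event == 1])
    r <- seq_len(d) - 1
    ll <- ll - sum(log(risk[g] - (r / d) * tied))
  }
  ll
}

#' @rdname breslow_loglik
#' @param ties `"breslow"`, `"efron"`, or `"auto"` (Efron when tied event
#'   times exist, Breslow otherwise).
#' @export
cox_partial_loglik <- function(eta, survival, ties = c("auto", "efron", "breslow")) {
  ties <- resolve_ties(ties, survival)
  if (ties == "efron") efron_loglik(eta, survival) else breslow_loglik(eta, survival)
}

resolve_ties <- function(ties, survival) {
  ties <- match.arg(ties, c("auto", "efron", "breslow"))
  if (ties != "auto") {
    return(ties)
  }
  ev_times <- survival$time[survival$event == 1]
  if (anyDuplicated(ev_times)) "efron" else "breslow"
}

# Gradient of the partial log-likelihood with respect to eta.
cox_grad <- function(eta, survival, ties = "breslow") {
  check_eta(eta, survival)
  p <- cox_prep(survival)
  n <- length(eta)
  et <- eta - max(eta)
  es <- exp(et[p$ord])
  risk <- rev(cumsum(rev(es)))[p$first]
  acc <- numeric(n) # risk-set coefficient seeds at group starts
  corr <- numeric(n) # own-group correction for tied events (Efron)
  for (g in seq_along(p$first)) {
    d <- p$d[g]
    if (d == 0) next
    if (ties == "breslow") {
      acc[p$first[g]] <- acc[p$first[g]] + d / risk[g]
    } else {
      tied <- sum(es[p$grp == g & p$event == 1])
      r <- seq_len(d) - 1
      denom <- risk[g] - (r / d) * tied
      a <- sum(1 / denom)
      bcoef <- sum((1 - r / d) / denom)
      acc[p$first[g]] <- acc[p$first[g]] + a
      corr[p$grp == g & p$event == 1] <- bcoef - a
    }
  }
  w <- cumsum(acc)
  g_sorted <- p$event - es * (w + corr)
  out <- numeric(n)
  out[p$ord] <- g_sorted
  out
}

#' Harrell's concordance index
#'
#' Among comparable pairs (the sample with the shorter time experienced an
#' event; pairs of events tied in time are excluded), returns the fraction in
#' which the higher linear predictor belongs to the shorter survival time,
#' counting ties in the predictor as 1/2.
#'
#' @inheritParams breslow_loglik
#' @return A scalar in `[0, 1]`.
#' @export
concordance_index <- function(eta, survival) {
  if (length(eta) != nrow(survival)) {
    abort("`eta` must have one value per sample in the survival table.")
  }
  time <- survival$time
  event <- survival$event
  lt <- outer(time, time, "<")
  eq <- outer(time, time, "==")
  ev_i <- matrix(event == 1, length(time), length(time))
  ev_j <- t(ev_i)
  comp <- (lt & ev_i) | (eq & ev_i & !ev_j)
  n_comp <- sum(comp)
  if (n_comp == 0) abort("no comparable pairs in the survival table.")
  conc <- outer(eta, eta, ">")
  tie <- outer(eta, eta, "==")
  (sum(comp & conc) + 0.5 * sum(comp & tie)) / n_comp
}

#' Breslow estimator of the cumulative baseline hazard
#'
#' @inheritParams breslow_loglik
#' @return A tibble with columns `time` (unique event times), `hazard`
#'   (increments), and `cumhaz`.
#' @export
breslow_baseline <- function(eta, survival) {
  check_eta(eta, survival)
  p <- cox_prep(survival)
  es <- exp(eta[p$ord] - max(eta))
  # Undo the stabilising shift so the baseline pairs with the raw eta scale.
  risk <- rev(cumsum(rev(es)))[p$first] * exp(max(eta))
  keep <- p$d > 0
  haz <- p$d[keep] / risk[keep]
  tibble::tibble(
    time = unique(p$time)[keep],
    hazard = haz,
    cumhaz = cumsum(haz)
  )
}

# Right-continuous step lookup of the cumulative baseline hazard.
cumhaz_at <- function(baseline, t) {
  i <- findInterval(t, baseline$time)
  c(0, baseline$cumhaz)[i + 1]
}

# Kaplan-Meier estimate of the censoring distribution G(t); returns right-
# continuous G(t) and the left limit G(t-).
km_censor <- function(survival) {
  sf <- survival::survfit(survival::Surv(survival$time, 1 - survival$event) ~ 1)
  times <- sf$time
  surv <- sf$surv
  list(
    at = function(t) c(1, surv)[findInterval(t, times) + 1],
    at_left = function(t) c(1, surv)[findInterval(t, times, left.open = TRUE) + 1]
  )
}

#' Integrated Brier score with inverse-probability-of-censoring weights
#'
#' Predicted survival curves are `S_b(t) = exp(-H0(t) * exp(eta_b))` with
#' `H0` the (Breslow) cumulative baseline hazard. The Brier score at each grid
#' time weights observed outcomes by the Kaplan-Meier estimate of the
#' censoring distribution, and the score is integrated over the grid by the
#' trapezoidal rule and normalised by the grid span.
#'
#' @inheritParams breslow_loglik
#' @param baseline Cumulative baseline hazard as returned by
#'   [breslow_baseline()] (typically estimated on training data). Defaults to
#'   the Breslow estimate on `survival` itself.
#' @param time_grid Evaluation grid; defaults to 100 evenly spaced points from
#'   the smallest observed time to the 80th percentile of observed times.
#' @param grid_size,upper_quantile Used to build the default grid.
#' @return The integrated Brier score, a scalar in `[0, 1]`.
#' @export
integrated_brier_score <- function(eta, survival, baseline = NULL,
                                   time_grid = NULL, grid_size = 100,
                                   upper_quantile = 0.8) {
  check_eta(eta, survival)
  baseline <- baseline %||% breslow_baseline(eta, survival)
  if (is.null(time_grid)) {
    lo <- min(survival$time)
    hi <- quantile(survival$time, upper_quantile, names = FALSE)
    if (hi <= lo) abort("degenerate default time grid; supply `time_grid`.")
    time_grid <- seq(lo, hi, length.out = grid_size)
  }
  G <- km_censor(survival)
  g_event <- G$at_left(survival$time)
  brier <- vapply(time_grid, function(t) {
    s_t <- exp(-cumhaz_at(baseline, t) * exp(eta))
    past_event <- survival$time <= t & survival$event == 1
    alive <- survival$time > t
    g_t <- G$at(t)
    if (any(past_event & g_event <= 0) || (any(alive) && g_t <= 0)) {
      abort(paste(
        "censoring-distribution estimate is zero at a required time;",
        "shorten `time_grid` (IPCW weights are undefined there)."
      ))
    }
    contrib <- numeric(length(eta))
    contrib[past_event] <- (0 - s_t[past_event])^2 / g_event[past_event]
    contrib[alive] <- (1 - s_t[alive])^2 / g_t
    mean(contrib)
  }, numeric(1))
  trapz(time_grid, brier) / diff(range(time_grid))
}
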