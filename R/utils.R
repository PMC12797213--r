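# Internal numeric helpers shared across modules.

#' @importFrom rlang %||% abort warn inform hash
#' @importFrom stats rnorm runif rbinom rgamma rpois quantile sd cor
NULL

# Numerically stable softplus: log(1 + exp(x)).
softplus <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))

# Inverse of softplus on (0, Inf); stable for both tails.
softplus_inv <- function(y) {
  stopifnot(all(y > 0))
  ifelse(y > 30, y, log(expm1(y)))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Evaluate `code` under a temporary RNG state so callers' streams are untouched.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Derive a stream-specific seed from a base seed; stays below 2^31.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483647L)
}

assert_count_matrix <- function(x, what = "counts") {
  if (!is.matrix(x) || !is.numeric(x)) {
    abort(sprintf("`%s` must be a numeric matrix.", what))
  }
  bad <- which(!is.finite(x) | x < 0 | x != round(x))
  if (length(bad)) {
    idx <- arrayInd(bad[1], dim(x))
    abort(sprintf(
      "`%s` must contain non-negative integers; first offending entry at row %d, column %d (value %s).",
      what, idx[1], idx[2], format(x[bad[1]])
    ))
  }
  invisible(x)
}

# Trapezoidal integration on an ordered grid.
trapz <- function(x, y) {
  n <- length(x)
  sum((y[-1] + y[-n]) / 2 * diff(x))
}
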