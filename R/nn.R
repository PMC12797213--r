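# Minimal dense feed-forward network with hand-derived backpropagation and an
# Adam optimiser. All model components here are small (2 hidden layers, tens to
# hundreds of units), so dense base-R matrix algebra is sufficient and keeps
# every gradient explicit. Hidden activations are ReLU; the output layer is
# linear and any head nonlinearity (softplus, softmax, exp) is applied -- and
# differentiated -- by the caller.

mlp_new <- function(d_in, hidden, d_out) {
  sizes <- c(d_in, hidden, d_out)
  n_layer <- length(sizes) - 1L
  W <- vector("list", n_layer)
  b <- vector("list", n_layer)
  for (l in seq_len(n_layer)) {
    fan_in <- sizes[l]
    # He initialisation for the ReLU layers, Glorot-ish scale for the output.
    sc <- if (l < n_layer) sqrt(2 / fan_in) else sqrt(1 / fan_in)
    W[[l]] <- matrix(rnorm(fan_in * sizes[l + 1]) * sc, fan_in, sizes[l + 1])
    b[[l]] <- numeric(sizes[l + 1])
  }
  structure(list(W = W, b = b, sizes = sizes), class = "chz_mlp")
}

# Forward pass. X is n x d_in. Returns the linear output plus the cache needed
# for the backward pass (layer inputs A and hidden pre-activations Z).
mlp_forward <- function(net, X) {
  n_layer <- length(net$W)
  A <- vector("list", n_layer)
  Z <- vector("list", n_layer)
  h <- X
  for (l in seq_len(n_layer)) {
    A[[l]] <- h
    z <- h %*% net$W[[l]]
    z <- sweep(z, 2, net$b[[l]], "+")
    Z[[l]] <- z
    h <- if (l < n_layer) pmax(z, 0) else z
  }
  list(out = h, A = A, Z = Z)
}

# Backward pass given d(loss)/d(linear output). Returns parameter gradients in
# the same shape as the network and the gradient with respect to the input.
mlp_backward <- function(net, cache, d_out) {
  n_layer <- length(net$W)
  gW <- vector("list", n_layer)
  gb <- vector("list", n_layer)
  d <- d_out
  for (l in rev(seq_len(n_layer))) {
    gW[[l]] <- crossprod(cache$A[[l]], d)
    gb[[l]] <- colSums(d)
    d <- d %*% t(net$W[[l]])
    if (l > 1L) d <- d * (cache$Z[[l - 1L]] > 0)
  }
  list(W = gW, b = gb, d_input = d)
}

mlp_params <- function(net) list(W = net$W, b = net$b)

mlp_set_params <- function(net, params) {
  net$W <- params$W
  net$b <- params$b
  net
}

# ---- Adam over arbitrary nested lists of numeric arrays ----

tree_zeros <- function(x) if (is.list(x)) lapply(x, tree_zeros) else x * 0

tree_map2 <- function(f, a, b) {
  if (is.list(a)) Map(function(x, y) tree_map2(f, x, y), a, b) else f(a, b)
}

tree_map3 <- function(f, a, b, c) {
  if (is.list(a)) {
    Map(function(x, y, z) tree_map3(f, x, y, z), a, b, c)
  } else {
    f(a, b, c)
  }
}

adam_new <- function(params) {
  list(m = tree_zeros(params), v = tree_zeros(params), t = 0L)
}

# One Adam update. `grads` holds the gradient of the *loss* (to be minimised).
adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- tree_map2(function(m, g) beta1 * m + (1 - beta1) * g, state$m, grads)
  state$v <- tree_map2(function(v, g) beta2 * v + (1 - beta2) * g^2, state$v, grads)
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  params <- tree_map3(
    function(p, m, v) p - lr * (m / c1) / (sqrt(v / c2) + eps),
    params, state$m, state$v
  )
  list(params = params, state = state)
}
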