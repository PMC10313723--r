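# Minimal fully-connected network with swish activations, written with
# explicit forward and vector-Jacobian-product passes. The closure framework
# needs VJPs with respect to both inputs (for the adjoint PDE source terms)
# and weights (for the parameter gradients), evaluated in batch across all
# grid nodes, which is what these routines provide.

swish <- function(x) x / (1 + exp(-x))
swish_grad <- function(x) {
  s <- 1 / (1 + exp(-x))
  s + x * s * (1 - s)
}

#' Create a fully-connected network
#'
#' Hidden layers use the smooth swish activation; the output layer is linear.
#' Weights are initialized with fan-in scaling, biases at zero.
#'
#' @param sizes integer vector of layer widths, input first, output last.
#' @param init_scale multiplier on the fan-in-scaled random initialization;
#'   0 gives an identically-zero network.
#' @return list of layers, each \code{list(W, b)}.
#' @keywords internal
mlp_create <- function(sizes, init_scale = 0.5) {
  n_lay <- length(sizes) - 1L
  lapply(seq_len(n_lay), function(l) {
    fan_in <- sizes[l]
    W <- matrix(stats::rnorm(sizes[l] * sizes[l + 1L], sd = init_scale / sqrt(fan_in)),
                sizes[l], sizes[l + 1L])
    list(W = W, b = numeric(sizes[l + 1L]))
  })
}

# forward pass; X is (batch x p_in). Returns list(out, cache) where cache
# holds pre-activations and activations for the backward pass.
mlp_forward <- function(layers, X) {
  n_lay <- length(layers)
  acts <- vector("list", n_lay + 1L)
  pres <- vector("list", n_lay)
  acts[[1L]] <- X
  for (l in seq_len(n_lay)) {
    Z <- acts[[l]] %*% layers[[l]]$W
    Z <- sweep(Z, 2L, layers[[l]]$b, `+`)
    pres[[l]] <- Z
    acts[[l + 1L]] <- if (l < n_lay) swish(Z) else Z
  }
  list(out = acts[[n_lay + 1L]], acts = acts, pres = pres)
}

# backward pass: G is (batch x p_out) cotangent of the output.
# Returns list(dX, grads) with grads[[l]] = list(W, b).
mlp_backward <- function(layers, fw, G) {
  n_lay <- length(layers)
  grads <- vector("list", n_lay)
  delta <- G
  for (l in n_lay:1L) {
    if (l < n_lay) delta <- delta * swish_grad(fw$pres[[l]])
    grads[[l]] <- list(W = crossprod(fw$acts[[l]], delta),
                       b = colSums(delta))
    delta <- delta %*% t(layers[[l]]$W)
  }
  list(dX = delta, grads = grads)
}

mlp_flatten <- function(layers) {
  unlist(lapply(layers, function(l) c(l$W, l$b)), use.names = FALSE)
}

mlp_unflatten <- function(layers, v) {
  pos <- 0L
  for (l in seq_along(layers)) {
    nw <- length(layers[[l]]$W)
    layers[[l]]$W[] <- v[pos + seq_len(nw)]
    pos <- pos + nw
    nb <- length(layers[[l]]$b)
    layers[[l]]$b[] <- v[pos + seq_len(nb)]
    pos <- pos + nb
  }
  layers
}
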