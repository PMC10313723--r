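# Closure models: interpretable linear combinations over a function library,
# and small fully-connected networks. Both are node-local: they map the
# state, its spatial derivatives, and static/exogenous parameters at a grid
# node to a tendency contribution at that same node. Closures are stored as
# environments so that several systems (e.g. training cases at different
# grid resolutions) can share one set of trainable weights.

#' Define one function-library term
#'
#' @param name unique term name (used in reports and serialized weights).
#' @param value function of the closure input bundle returning the feature
#'   field (one value per node).
#' @param grads list of partial derivatives of the feature with respect to
#'   its inputs: each element \code{list(state =, order =, fn =)} gives
#'   d(feature)/d(d^order state / dx^order) as a function of the bundle.
#' @return a \code{"library_term"}.
#' @export
library_term <- function(name, value, grads) {
  structure(list(name = name, value = value, grads = grads),
            class = "library_term")
}

#' Assemble a function library
#' @param ... \code{\link{library_term}} objects.
#' @return a \code{"function_library"} (ordered, unique names).
#' @export
function_library <- function(...) {
  terms <- list(...)
  nms <- vapply(terms, `[[`, character(1), "name")
  if (anyDuplicated(nms)) stop("library term names must be unique")
  structure(list(terms = terms, names = nms), class = "function_library")
}

lib_orders_needed <- function(lib) {
  ords <- integer(0)
  for (tm in lib$terms) {
    for (g in tm$grads) ords <- c(ords, g$order)
  }
  sort(unique(ords[ords > 0L]))
}

#' Evaluate library features node-wise
#'
#' @param env closure input bundle: \code{u} (nodes x states matrix),
#'   \code{d} (per state, per derivative order fields), \code{params},
#'   \code{exo}.
#' @param lib a \code{\link{function_library}}.
#' @return matrix nodes x terms.
#' @export
build_features <- function(env, lib) {
  cols <- lapply(lib$terms, function(tm) {
    out <- tryCatch(tm$value(env), error = function(e) {
      stop("feature '", tm$name, "': ", conditionMessage(e))
    })
    if (is.null(out) || anyNA(out)) stop("feature '", tm$name,
                                         "' is missing a derivative input")
    out
  })
  do.call(cbind, cols)
}

# derivative field accessor used inside library terms
env_d <- function(env, state, order) {
  if (order == 0L) return(env$u[, state])
  d <- env$d[[state]][[order]]
  if (is.null(d)) stop("derivative of order ", order, " not provided")
  d
}

#' Linear library closure
#'
#' A neural network with no hidden layer and linear activation: the closure
#' is \code{features \%*\% W \%*\% t(channel_map)}. The channel map encodes
#' hard output constraints (e.g. biomass conservation) as fixed linear
#' relations between raw outputs and state tendencies, so constrained
#' combinations hold exactly at every node and every call.
#'
#' @param lib a \code{\link{function_library}}.
#' @param n_raw number of free output channels per term.
#' @param channel_map numeric matrix (n_states x n_raw); default identity.
#' @param n_states number of state variables (defaults to rows of
#'   \code{channel_map}, or 1).
#' @return closure environment of class \code{"closure_linear"}.
#' @export
closure_linear <- function(lib, n_raw = 1L, channel_map = NULL, n_states = NULL) {
  if (is.null(channel_map)) {
    if (is.null(n_states)) n_states <- n_raw
    channel_map <- diag(1, n_states, n_raw)
  }
  channel_map <- as.matrix(channel_map)
  if (ncol(channel_map) != n_raw) stop("channel map inconsistent with channel count")
  K <- length(lib$terms)
  cl <- new.env(parent = emptyenv())
  cl$kind <- "linear"
  cl$lib <- lib
  cl$W <- matrix(0, K, n_raw)
  cl$frozen <- matrix(FALSE, K, n_raw)
  cl$A <- channel_map
  cl$n_states <- nrow(channel_map)
  cl$prunable <- TRUE
  rn <- if (n_raw > 1L) paste0(rep(lib$names, n_raw), ".",
                               rep(seq_len(n_raw), each = K)) else lib$names
  cl$w_names <- rn
  class(cl) <- c("closure_linear", "closure")
  cl
}

#' Deep (fully-connected) closure
#'
#' @param inputs list of input descriptors:
#'   \code{list(kind = "state"|"deriv"|"param"|"exo", state =, order =,
#'   name =, center =, scale =)}. State/derivative inputs are standardized
#'   by the fixed \code{center}/\code{scale}.
#' @param hidden integer vector of hidden-layer widths.
#' @param n_raw number of raw output channels.
#' @param channel_map numeric matrix (n_states x n_raw) applied after
#'   gating; default identity.
#' @param gate_state optional state index: output is multiplied node-wise by
#'   \code{|u[, gate_state]|}, so it vanishes exactly wherever that state
#'   does.
#' @param init_scale initialization scale (0 gives the zero closure).
#' @param out_clamp optional smooth bound on each raw output channel
#'   (\code{c * tanh(x / c)}): near zero the map is the identity, but the
#'   closure tendency can never exceed \code{c} in magnitude, which keeps
#'   long extrapolations outside the training regime bounded.
#' @return closure environment of class \code{"closure_deep"}.
#' @export
closure_deep <- function(inputs, hidden, n_raw = 1L, channel_map = NULL,
                         gate_state = NULL, init_scale = 0.5,
                         out_clamp = NULL) {
  if (is.null(channel_map)) channel_map <- diag(1, n_raw, n_raw)
  channel_map <- as.matrix(channel_map)
  if (ncol(channel_map) != n_raw) stop("channel map inconsistent with channel count")
  cl <- new.env(parent = emptyenv())
  cl$kind <- "deep"
  cl$inputs <- inputs
  cl$layers <- mlp_create(c(length(inputs), hidden, n_raw), init_scale)
  cl$A <- channel_map
  cl$n_states <- nrow(channel_map)
  cl$gate_state <- gate_state
  cl$out_clamp <- out_clamp
  cl$prunable <- FALSE
  cl$w_names <- paste0("theta", seq_along(mlp_flatten(cl$layers)))
  class(cl) <- c("closure_deep", "closure")
  cl
}

closure_orders_needed <- function(cl) {
  if (cl$kind == "linear") return(lib_orders_needed(cl$lib))
  ords <- integer(0)
  for (inp in cl$inputs) {
    if (inp$kind == "deriv") ords <- c(ords, inp$order)
  }
  sort(unique(ords))
}

deep_input_matrix <- function(cl, env) {
  X <- matrix(0, nrow(env$u), length(cl$inputs))
  for (j in seq_along(cl$inputs)) {
    inp <- cl$inputs[[j]]
    raw <- switch(inp$kind,
      state = env$u[, inp$state],
      deriv = env_d(env, inp$state, inp$order),
      param = rep(env$params[[inp$name]], nrow(env$u)),
      exo   = env$exo[[inp$name]],
      stop("unknown input kind"))
    ctr <- if (is.null(inp$center)) 0 else inp$center
    scl <- if (is.null(inp$scale)) 1 else inp$scale
    X[, j] <- (raw - ctr) / scl
  }
  X
}

#' Evaluate a closure model
#'
#' @param cl a closure from \code{\link{closure_linear}} or
#'   \code{\link{closure_deep}}.
#' @param env closure input bundle (see \code{\link{build_features}}).
#' @return tendency contribution, matrix nodes x states.
#' @export
closure_eval <- function(cl, env) {
  if (cl$kind == "linear") {
    FT <- build_features(env, cl$lib)
    return((FT %*% cl$W) %*% t(cl$A))
  }
  X <- deep_input_matrix(cl, env)
  fw <- mlp_forward(cl$layers, X)
  out <- fw$out
  if (!is.null(cl$out_clamp)) out <- cl$out_clamp * tanh(out / cl$out_clamp)
  if (!is.null(cl$gate_state)) out <- out * abs(env$u[, cl$gate_state])
  out %*% t(cl$A)
}

# Joint vector-Jacobian product of a closure: given the adjoint field `lam`
# (nodes x states), returns the cotangent with respect to the state
# (including through spatial-derivative inputs, using the transposed free
# operators in env$opT) and the flattened weight gradient.
closure_vjp <- function(cl, env, lam, want_dw = TRUE) {
  S <- lam %*% cl$A                      # nodes x n_raw
  n <- nrow(env$u)
  du <- matrix(0, n, ncol(env$u))
  if (cl$kind == "linear") {
    FT <- build_features(env, cl$lib)
    dW <- if (want_dw) {
      tmp <- crossprod(FT, S)
      tmp[cl$frozen] <- 0
      tmp
    } else NULL
    for (k in seq_along(cl$lib$terms)) {
      gk <- drop(S %*% cl$W[k, ])
      for (g in cl$lib$terms[[k]]$grads) {
        cfield <- gk * g$fn(env)
        if (g$order == 0L) {
          du[, g$state] <- du[, g$state] + cfield
        } else {
          du[, g$state] <- du[, g$state] + env$opT(g$order, cfield)
        }
      }
    }
    return(list(du = du, dw = if (want_dw) as.numeric(dW) else NULL))
  }
  X <- deep_input_matrix(cl, env)
  fw <- mlp_forward(cl$layers, X)
  out_pre <- fw$out
  out_post <- if (!is.null(cl$out_clamp))
    cl$out_clamp * tanh(out_pre / cl$out_clamp) else out_pre
  Gout <- S
  if (!is.null(cl$gate_state)) {
    gf <- abs(env$u[, cl$gate_state])
    Gout <- S * gf
    dgate <- rowSums(S * out_post) * sign(env$u[, cl$gate_state])
    du[, cl$gate_state] <- du[, cl$gate_state] + dgate
  }
  if (!is.null(cl$out_clamp)) {
    Gout <- Gout * (1 - tanh(out_pre / cl$out_clamp)^2)
  }
  bk <- mlp_backward(cl$layers, fw, Gout)
  for (j in seq_along(cl$inputs)) {
    inp <- cl$inputs[[j]]
    if (!inp$kind %in% c("state", "deriv")) next
    scl <- if (is.null(inp$scale)) 1 else inp$scale
    col <- bk$dX[, j] / scl
    if (inp$kind == "state") {
      du[, inp$state] <- du[, inp$state] + col
    } else {
      du[, inp$state] <- du[, inp$state] + env$opT(inp$order, col)
    }
  }
  dw <- unlist(lapply(bk$grads, function(g) c(g$W, g$b)), use.names = FALSE)
  list(du = du, dw = dw)
}

#' Get the flattened trainable weights of a closure
#' @param cl a closure.
#' @return numeric vector.
#' @export
closure_get_w <- function(cl) {
  if (cl$kind == "linear") as.numeric(cl$W) else mlp_flatten(cl$layers)
}

#' Set the flattened trainable weights of a closure
#' @param cl a closure.
#' @param v numeric vector (same layout as \code{closure_get_w}).
#' @return the closure, invisibly.
#' @export
closure_set_w <- function(cl, v) {
  if (cl$kind == "linear") {
    cl$W[] <- v
    cl$W[cl$frozen] <- 0
  } else {
    cl$layers <- mlp_unflatten(cl$layers, v)
  }
  invisible(cl)
}

closure_n_w <- function(cl) length(closure_get_w(cl))

#' Regularization penalty and weight pruning
#'
#' Computes \code{l1 * sum|w| + l2 * sum(w^2)} over the trainable weights
#' and, for prunable (library) closures with \code{l1 > 0}, permanently
#' zeroes and freezes weights whose magnitude has dropped below
#' \code{threshold}. Frozen weights stay zero for the rest of training.
#'
#' @param cl a closure.
#' @param l1,l2 penalty weights (>= 0).
#' @param threshold pruning threshold (>= 0).
#' @param prune whether to apply pruning on this call (the trainer enables
#'   it only after an initial burn-in, so zero-initialized weights are not
#'   pruned before they have moved).
#' @return list with \code{penalty} and \code{n_pruned}.
#' @export
prune_and_penalty <- function(cl, l1 = 0, l2 = 0, threshold = 0, prune = TRUE) {
  stopifnot(threshold >= 0)
  w <- closure_get_w(cl)
  if (cl$kind == "linear") w <- w[!as.logical(cl$frozen)]
  pen <- l1 * sum(abs(w)) + l2 * sum(w^2)
  n_pruned <- 0L
  if (prune && isTRUE(cl$prunable) && l1 > 0 && threshold > 0) {
    kill <- !cl$frozen & abs(cl$W) < threshold
    n_pruned <- sum(kill)
    if (n_pruned > 0L) {
      cl$W[kill] <- 0
      cl$frozen[kill] <- TRUE
    }
  }
  list(penalty = pen, n_pruned = n_pruned)
}

# gradient of the regularization penalty at the current weights
penalty_grad <- function(cl, l1, l2) {
  w <- closure_get_w(cl)
  g <- l1 * sign(w) + 2 * l2 * w
  if (cl$kind == "linear") g[as.logical(cl$frozen)] <- 0
  g
}

#' Named coefficient report for a linear closure
#' @param cl a \code{closure_linear}.
#' @return named numeric vector (or matrix for multi-channel closures).
#' @export
closure_coefficients <- function(cl) {
  if (cl$kind != "linear") stop("coefficients are defined for linear closures")
  if (ncol(cl$W) == 1L) stats::setNames(as.numeric(cl$W), cl$lib$names)
  else {
    out <- cl$W
    rownames(out) <- cl$lib$names
    out
  }
}
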