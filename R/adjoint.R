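# Continuous-adjoint machinery. The forward model is solved once and stored
# with a cubic Hermite interpolant; the adjoint fields (lambda for the state,
# mu for the memory state) are then integrated backward from the final time,
# with the data-misfit loss terms entering as jump updates to lambda at each
# snapshot time. Spatial transposes in the adjoint PDE (the alternating-sign
# integration-by-parts pattern) are realized as exact transposes of the
# forward finite-difference operators, including their boundary closure, so
# adjoint gradients agree with finite differences of the discrete loss up to
# time-integration and interpolation error. Weight gradients are accumulated
# during the same backward sweep by trapezoid quadrature, with one-sided
# integrand values at the snapshot times where the adjoint jumps.

#' Loss specification
#'
#' Two snapshot-misfit losses: plain space-and-time averaged mean absolute
#' error, and the multi-state scaled form
#' \code{mean_i (1/D) int sqrt( sum_B |err_B| / sigma_B ) dz} used for the
#' plankton-carbonate column, where the per-state scalings \code{sigma}
#' balance states of different magnitudes.
#'
#' @param kind "mae" or "scaled_sqrt".
#' @param sigma per-state scalings (scaled_sqrt only), positive.
#' @param eps smoothing floor inside the square root.
#' @return a \code{"loss_spec"}.
#' @export
loss_spec <- function(kind = c("mae", "scaled_sqrt"), sigma = NULL,
                      eps = 1e-12) {
  kind <- match.arg(kind)
  if (kind == "scaled_sqrt") {
    if (is.null(sigma) || any(sigma <= 0)) stop("sigma must be positive")
  }
  structure(list(kind = kind, sigma = sigma, eps = eps), class = "loss_spec")
}

# trapezoid quadrature weights over the grid; sum(wq) = |Omega|
grid_quad_weights <- function(grid) {
  wq <- rep(grid$dx, grid$n)
  wq[c(1, grid$n)] <- grid$dx / 2
  wq
}

snapshot_loss <- function(err, spec, wq, omega) {
  if (spec$kind == "mae") {
    sum(wq * rowSums(abs(err))) / omega
  } else {
    s <- sweep(abs(err), 2L, spec$sigma, `/`)
    sum(wq * sqrt(rowSums(s) + spec$eps)) / omega
  }
}

snapshot_loss_grad <- function(err, spec, wq, omega) {
  if (spec$kind == "mae") {
    sign(err) * (wq / omega)
  } else {
    s <- sweep(abs(err), 2L, spec$sigma, `/`)
    r <- 0.5 / sqrt(rowSums(s) + spec$eps)
    sweep(sign(err), 2L, spec$sigma, `/`) * (r * wq / omega)
  }
}

#' Evaluate the snapshot loss of a trajectory against data
#'
#' @param traj forward \code{"pde_trajectory"}.
#' @param data a \code{\link{closure_dataset}}.
#' @param spec a \code{\link{loss_spec}}.
#' @param t_min,t_max restrict to data times in \code{(t_min, t_max]}.
#' @return scalar loss (average over the selected snapshots).
#' @export
loss_eval <- function(traj, data, spec, t_min = -Inf, t_max = Inf) {
  sel <- which(data$times > t_min + 1e-12 & data$times <= t_max + 1e-12)
  if (!length(sel)) stop("no data times in the requested window")
  wq <- grid_quad_weights(data$grid)
  omega <- sum(wq)
  tot <- 0
  for (i in sel) {
    err <- traj_state(traj, data$times[i]) - data$U[, , i]
    tot <- tot + snapshot_loss(err, spec, wq, omega)
  }
  tot / length(sel)
}

# collect trainable closures of a system (shared environments)
sys_closures <- function(sys) {
  out <- list()
  if (!is.null(sys$markov)) out$markov <- sys$markov
  if (!is.null(sys$nonmarkov)) out$nonmark <- sys$nonmarkov$cl
  out
}

closures_get_w <- function(cls) unlist(lapply(cls, closure_get_w), use.names = FALSE)

closures_set_w <- function(cls, v) {
  pos <- 0L
  for (cl in cls) {
    k <- closure_n_w(cl)
    closure_set_w(cl, v[pos + seq_len(k)])
    pos <- pos + k
  }
  invisible(cls)
}

# merge times that differ only by floating-point representation noise
snap_times <- function(x, tol = 1e-9) {
  x <- sort(x)
  keep <- c(TRUE, diff(x) > tol)
  x[keep]
}

# evaluation context shared by the Jacobian assembler and the gradient
# integrand at one backward time node
adj_ctx <- function(sys, traj, t) {
  U <- traj_state(traj, t)
  list(t = t, U = U, env = closure_env_at(sys, U, t), n = sys$n,
       cache = new.env(parent = emptyenv()))
}

ctx_features <- function(ctx, cl) {
  if (is.null(ctx$cache$FT)) ctx$cache$FT <- build_features(ctx$env, cl$lib)
  ctx$cache$FT
}

# The backward adjoint pass. `t0` is the window start (the state there is
# fixed data, so no jump is applied at t0); data times in (t0, t1] act as
# jump sources.
adjoint_pass <- function(sys, traj, data, spec, t0 = NULL, t1 = NULL,
                         keep = FALSE) {
  if (is.null(t0)) t0 <- traj$times[1]
  if (is.null(t1)) t1 <- traj$times[length(traj$times)]
  sel <- which(data$times > t0 + 1e-12 & data$times <= t1 + 1e-12)
  if (!length(sel)) stop("no data times inside the adjoint window")
  tdat <- data$times[sel]
  M <- length(sel)
  wq <- grid_quad_weights(data$grid)
  omega <- sum(wq)
  n <- sys$n; ns <- sys$ns; ndof <- n * ns
  has_delay <- !is.null(sys$nonmarkov) && sys$nonmarkov$tau > 0
  tau <- if (has_delay) sys$nonmarkov$tau else 0
  if (is.null(sys$jt)) stop("system has no transposed-Jacobian assembler")

  vecm <- function(M_) vec_state(M_, sys$interleave)
  matm <- function(v) mat_state(v, n, ns, sys$interleave)

  cls <- sys_closures(sys)
  g_markov <- if (!is.null(cls$markov)) numeric(closure_n_w(cls$markov)) else NULL
  g_nonmark <- if (!is.null(cls$nonmark)) numeric(closure_n_w(cls$nonmark)) else NULL

  # backward step grid: breakpoints at data times, subdivided by adj_dt
  bp <- rev(snap_times(c(t0, tdat, t1)))
  jump_used <- logical(M)
  step_times <- list()
  for (i in seq_len(length(bp) - 1L)) {
    nsub <- max(1L, ceiling((bp[i] - bp[i + 1L]) / sys$solver$adj_dt - 1e-9))
    step_times[[i]] <- seq(bp[i], bp[i + 1L], length.out = nsub + 1L)
  }
  n_nodes <- length(unique(unlist(step_times)))

  aU <- matrix(0, n, ns)
  aY <- if (has_delay) matrix(0, n, ns) else NULL
  keep_any <- keep || has_delay
  if (keep_any) {
    storeL <- matrix(0, n_nodes, ndof)
    storeM <- if (has_delay) matrix(0, n_nodes, ndof) else NULL
    store_t <- numeric(n_nodes)
  }
  node_ctr <- 0L

  mask <- function(A) {
    if (!is.null(sys$core$pinned)) A[sys$core$pinned] <- 0
    A
  }
  # linear interpolation in the already-stored (descending-time) segment
  aY_at <- function(t) {
    if (t > t1 + 1e-12 || node_ctr == 0L) return(matrix(0, n, ns))
    ts <- store_t[seq_len(node_ctr)]      # descending
    if (t >= ts[1]) return(matm(storeM[1, ]))
    k <- findInterval(-t, -ts)            # ts descending
    if (k >= node_ctr) return(matm(storeM[node_ctr, ]))
    w <- (ts[k] - t) / (ts[k] - ts[k + 1L])
    matm((1 - w) * storeM[k, ] + w * storeM[k + 1L, ])
  }

  apply_jump <- function(t) {
    i_dat <- which(abs(tdat - t) < 1e-9 & !jump_used)
    for (i in i_dat) {
      jump_used[i] <<- TRUE
      err <- traj_state(traj, tdat[i]) - data$U[, , sel[i]]
      aU <<- mask(aU + snapshot_loss_grad(err, spec, wq, omega) / M)
    }
  }
  push_node <- function(t) {
    node_ctr <<- node_ctr + 1L
    if (keep_any) {
      store_t[node_ctr] <<- t
      storeL[node_ctr, ] <<- vecm(aU)
      if (has_delay) storeM[node_ctr, ] <<- vecm(aY)
    }
  }

  # gradient integrand at a node, with the CURRENT adjoint values
  grad_integrand <- function(ctx) {
    out <- list(m = NULL, d = NULL)
    if (!is.null(cls$markov)) {
      if (cls$markov$kind == "linear") {
        gm <- as.numeric(crossprod(ctx_features(ctx, cls$markov),
                                   aU %*% cls$markov$A))
        gm[as.logical(cls$markov$frozen)] <- 0
        out$m <- gm
      } else {
        out$m <- closure_vjp(cls$markov, ctx$env, aU)$dw
      }
    }
    if (has_delay) {
      gd <- closure_vjp(cls$nonmark, ctx$env, aY)$dw
      td <- ctx$t - tau
      Udel <- if (td <= traj$times[1] + 1e-12) sys$nonmarkov$history(td)
              else traj_state(traj, td)
      env_del <- closure_env_at(sys, Udel, td)
      out$d <- gd - closure_vjp(cls$nonmark, env_del, aY)$dw
    }
    out
  }

  push_node(bp[1])      # stored adjoint at T is the terminal value (zero)
  apply_jump(bp[1])
  ctx <- adj_ctx(sys, traj, bp[1])
  gprev <- grad_integrand(ctx)

  for (seg in seq_along(step_times)) {
    tt <- step_times[[seg]]
    for (i in seq_len(length(tt) - 1L)) {
      t_here <- tt[i]; t_next <- tt[i + 1L]
      h <- t_next - t_here                 # negative
      JT <- sys$jt(ctx)
      srcU <- matrix(0, n, ns)
      if (has_delay) {
        wdel <- aY - aY_at(t_here + tau)
        srcU <- closure_vjp(cls$nonmark, ctx$env, wdel, want_dw = FALSE)$du
      }
      fU <- function(a_U) mask(-(matm(drop(JT %*% vecm(a_U))) + srcU))
      if (has_delay) {
        k1U <- fU(aU); k1Y <- -aU
        k2U <- fU(aU + h / 2 * k1U); k2Y <- -(aU + h / 2 * k1U)
        k3U <- fU(aU + h / 2 * k2U); k3Y <- -(aU + h / 2 * k2U)
        k4U <- fU(aU + h * k3U); k4Y <- -(aU + h * k3U)
        aU <- mask(aU + h / 6 * (k1U + 2 * k2U + 2 * k3U + k4U))
        aY <- aY + h / 6 * (k1Y + 2 * k2Y + 2 * k3Y + k4Y)
      } else {
        k1 <- fU(aU)
        k2 <- fU(aU + h / 2 * k1)
        k3 <- fU(aU + h / 2 * k2)
        k4 <- fU(aU + h * k3)
        aU <- mask(aU + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4))
      }
      ctx <- adj_ctx(sys, traj, t_next)
      # trapezoid with the pre-jump adjoint at the lower endpoint
      gcur <- grad_integrand(ctx)
      w2 <- abs(h) / 2
      if (!is.null(g_markov)) g_markov <- g_markov + w2 * (gprev$m + gcur$m)
      if (!is.null(g_nonmark)) g_nonmark <- g_nonmark + w2 * (gprev$d + gcur$d)
      is_bp <- (i == length(tt) - 1L)
      if (is_bp) apply_jump(t_next)
      push_node(t_next)
      gprev <- if (is_bp) grad_integrand(ctx) else gcur
    }
  }

  # history contribution of the delay kernel through y(t0)
  if (has_delay && !is.null(g_nonmark)) {
    nm <- sys$nonmarkov
    ss <- seq(t0 - tau, t0, length.out = nm$quad_n)
    hh <- ss[2] - ss[1]
    wt <- rep(hh, nm$quad_n); wt[c(1, nm$quad_n)] <- hh / 2
    for (i in seq_along(ss)) {
      env_h <- closure_env_at(sys, nm$history(ss[i]), ss[i])
      g_nonmark <- g_nonmark + wt[i] * closure_vjp(cls$nonmark, env_h, aY)$dw
    }
  }

  adj <- NULL
  if (keep) {
    ord <- rev(seq_len(node_ctr))
    adj <- structure(list(times = store_t[ord],
                          lambda = storeL[ord, , drop = FALSE],
                          mu = if (has_delay) storeM[ord, , drop = FALSE] else NULL,
                          n = n, ns = ns, interleave = sys$interleave),
                     class = "adjoint_trajectory")
  }
  list(g_markov = g_markov, g_nonmark = g_nonmark, adj = adj,
       aU0 = aU, aY0 = aY)
}

#' Solve the adjoint equations backward in time
#'
#' @param sys an \code{\link{npdde_system}}.
#' @param traj forward trajectory covering \code{[t0, t1]}.
#' @param data a \code{\link{closure_dataset}}.
#' @param spec a \code{\link{loss_spec}}.
#' @param t0,t1 adjoint window (defaults: the trajectory span).
#' @return an \code{"adjoint_trajectory"} with \code{times}, \code{lambda}
#'   (state adjoint) and \code{mu} (memory adjoint, delay systems only).
#' @export
solve_adjoint <- function(sys, traj, data, spec, t0 = NULL, t1 = NULL) {
  adjoint_pass(sys, traj, data, spec, t0, t1, keep = TRUE)$adj
}

#' Assemble weight gradients from forward and adjoint solves
#'
#' @inheritParams solve_adjoint
#' @return list with \code{markov} and \code{nonmark} gradient vectors.
#' @export
assemble_gradients <- function(sys, traj, data, spec, t0 = NULL, t1 = NULL) {
  res <- adjoint_pass(sys, traj, data, spec, t0, t1, keep = FALSE)
  list(markov = res$g_markov, nonmark = res$g_nonmark)
}

#' Compare adjoint gradients with central finite differences
#'
#' Independent oracle for the adjoint machinery: perturbs sampled weights,
#' re-solves the forward model, and differences the loss.
#'
#' @param sys an \code{\link{npdde_system}} (weights are restored on exit).
#' @param data a \code{\link{closure_dataset}}.
#' @param spec a \code{\link{loss_spec}}.
#' @param U0 initial state for the forward solve.
#' @param t0,t1 window.
#' @param n_sample number of weights to test (sampled without replacement).
#' @param h_fd finite-difference step.
#' @return list with \code{max_rel_err}, per-weight table.
#' @export
gradient_check <- function(sys, data, spec, U0, t0, t1, n_sample = 5L,
                           h_fd = 1e-5) {
  cls <- sys_closures(sys)
  w0 <- closures_get_w(cls)
  tgrid <- snap_times(c(seq(t0, t1, length.out = 21L),
                        data$times[data$times > t0 & data$times <= t1 + 1e-12]))
  fwd <- function() solve_forward(sys, U0, tgrid)
  traj <- fwd()
  res <- adjoint_pass(sys, traj, data, spec, t0, t1)
  g_adj <- c(res$g_markov, res$g_nonmark)
  nw <- length(w0)
  idx <- if (nw <= n_sample) seq_len(nw) else sort(sample.int(nw, n_sample))
  g_fd <- numeric(length(idx))
  for (k in seq_along(idx)) {
    wp <- w0; wp[idx[k]] <- wp[idx[k]] + h_fd
    closures_set_w(cls, wp)
    lp <- loss_eval(fwd(), data, spec, t_min = t0, t_max = t1)
    wm <- w0; wm[idx[k]] <- wm[idx[k]] - h_fd
    closures_set_w(cls, wm)
    lm <- loss_eval(fwd(), data, spec, t_min = t0, t_max = t1)
    g_fd[k] <- (lp - lm) / (2 * h_fd)
    closures_set_w(cls, w0)
  }
  denom <- pmax(abs(g_fd), abs(g_adj[idx]), 1e-8)
  rel <- abs(g_adj[idx] - g_fd) / denom
  list(max_rel_err = max(rel),
       table = data.frame(index = idx, adjoint = g_adj[idx], fd = g_fd,
                          rel_err = rel))
}
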