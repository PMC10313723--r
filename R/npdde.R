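# Forward model: a low-fidelity PDE right-hand side augmented with an
# instantaneous (Markovian) closure and, optionally, a distributed-delay
# (non-Markovian) closure. The delay integral over [t - tau, t] is carried
# as an extra memory state y per affected channel:
#   du/dt = L(u) + F(u) + y
#   dy/dt = G(u(t), t) - G(u(t - tau), t - tau),  y(0) = integral of G over
#                                                 the history window
# which is the discrete-delay form equivalent to the distributed-delay
# closure. G is the channel-mapped output of the delay kernel network.

vec_state <- function(U, interleave) {
  if (is.null(dim(U))) return(as.numeric(U))
  if (interleave) as.numeric(t(U)) else as.numeric(U)
}

mat_state <- function(y, n, ns, interleave) {
  if (ns == 1L) return(matrix(y, n, 1L))
  if (interleave) t(matrix(y, ns, n)) else matrix(y, n, ns)
}

#' Assemble a neural partial (delay) differential equation system
#'
#' @param grid a \code{\link{grid1d}}.
#' @param state_names character vector of state names.
#' @param core low-fidelity model: \code{list(eval = function(t, U, sys),
#'   jacT = function(t, U, sys) [sparse transposed Jacobian], pinned =
#'   logical matrix of Dirichlet-pinned nodes or NULL)}.
#' @param markov optional Markovian closure (see \code{\link{closure_linear}},
#'   \code{\link{closure_deep}}).
#' @param nonmarkov optional list \code{list(cl = deep closure, tau = delay,
#'   history = function(t) state matrix for t <= t0, quad_n = 33)}.
#' @param params static parameters exposed to closures (always includes
#'   \code{dx}).
#' @param exo_fn optional \code{function(t)} returning a list of exogenous
#'   node fields (e.g. irradiance) exposed to closures.
#' @param solver list of solver settings: \code{method}, \code{rtol},
#'   \code{atol}, \code{bands} (band halfwidth for banded Jacobians),
#'   \code{adj_dt} (backward adjoint step).
#' @return object of class \code{"npdde_system"}.
#' @export
npdde_system <- function(grid, state_names, core, markov = NULL,
                         nonmarkov = NULL, params = list(), exo_fn = NULL,
                         solver = list()) {
  ns <- length(state_names)
  sv <- utils::modifyList(list(method = "bdf", rtol = 1e-6, atol = 1e-8,
                               bands = NULL, adj_dt = 1e-3), solver)
  params$dx <- grid$dx
  orders <- integer(0)
  if (!is.null(markov)) orders <- c(orders, closure_orders_needed(markov))
  if (!is.null(nonmarkov)) orders <- c(orders, closure_orders_needed(nonmarkov$cl))
  orders <- sort(unique(orders))
  # closure-input derivatives: interior 4th-order central stencils, with
  # the closure features set to zero at boundary-adjacent nodes where the
  # centred stencil does not fit (one-sided extrapolatory rows there feed
  # boundary errors into the interior; near the boundaries the resolved
  # model terms carry the dynamics alone)
  free_ops <- list()
  for (o in orders) {
    op <- deriv_operator(grid, fd_scheme("central", 4L, o))
    nz <- central_halfwidth(o, 4L)
    op$D[seq_len(nz), ] <- 0
    op$D[grid$n - seq_len(nz) + 1L, ] <- 0
    op$Dt <- Matrix::t(op$D)
    free_ops[[o]] <- op
  }
  if (!is.null(nonmarkov)) {
    nonmarkov <- utils::modifyList(list(quad_n = 33L), nonmarkov)
    if (nonmarkov$tau < 0) stop("tau must be non-negative")
  }
  sys <- list(grid = grid, n = grid$n, ns = ns, state_names = state_names,
              core = core, markov = markov, nonmarkov = nonmarkov,
              params = params, exo_fn = exo_fn, solver = sv,
              free_ops = free_ops, orders = orders,
              interleave = ns > 1L)
  class(sys) <- "npdde_system"
  if (!is.null(core$jt_parts)) {
    parts <- core$jt_parts(sys)
    if (!is.null(markov)) {
      if (markov$kind != "linear") {
        stop("deep Markovian closures are not supported by the adjoint assembler")
      }
      parts <- c(parts, linear_closure_jt_parts(markov, sys))
    }
    sys$jt <- make_jt_assembler(parts, sys$n, ns, sys$interleave)
  }
  sys
}

# closure input bundle at (t, U)
closure_env_at <- function(sys, U, t) {
  d <- NULL
  if (length(sys$orders)) {
    d <- vector("list", sys$ns)
    for (s in seq_len(sys$ns)) {
      d[[s]] <- vector("list", max(sys$orders))
      for (o in sys$orders) {
        d[[s]][[o]] <- apply_op(sys$free_ops[[o]], U[, s])
      }
    }
  }
  list(u = U, d = d, params = sys$params,
       exo = if (is.null(sys$exo_fn)) list() else sys$exo_fn(t),
       t = t,
       opT = function(order, v) apply_opT(sys$free_ops[[order]], v))
}

# mapped delay-kernel output G(t, U)
nonmarkov_G <- function(sys, U, t) {
  closure_eval(sys$nonmarkov$cl, closure_env_at(sys, U, t))
}

#' Initial memory state from the history function
#'
#' Integrates the delay kernel over the history window \code{[t0 - tau, t0]}
#' by composite trapezoid quadrature.
#'
#' @param sys an \code{\link{npdde_system}} with a non-Markovian term.
#' @param t0 start time of the forward solve.
#' @return memory field (nodes x states).
#' @export
history_integral <- function(sys, t0 = 0) {
  y0 <- matrix(0, sys$n, sys$ns)
  nm <- sys$nonmarkov
  if (is.null(nm)) return(y0)
  if (nm$tau <= 0) {
    warning("tau <= 0 with a delay kernel present; memory state is zero")
    return(y0)
  }
  ss <- seq(t0 - nm$tau, t0, length.out = nm$quad_n)
  h <- ss[2] - ss[1]
  w <- rep(h, nm$quad_n); w[c(1, nm$quad_n)] <- h / 2
  for (i in seq_along(ss)) {
    y0 <- y0 + w[i] * nonmarkov_G(sys, nm$history(ss[i]), ss[i])
  }
  y0
}

#' Right-hand side of the coupled state/memory system
#'
#' @param t time.
#' @param U state matrix (nodes x states).
#' @param Y memory matrix (nodes x states); ignored without a delay term.
#' @param sys an \code{\link{npdde_system}}.
#' @param delayed_lookup function of time returning the state matrix at
#'   \code{t - tau} (from the history for \code{t - tau <= t0}, from the
#'   running trajectory interpolant otherwise).
#' @return list \code{(dU, dY)}.
#' @export
augmented_rhs <- function(t, U, Y, sys, delayed_lookup = NULL) {
  dU <- sys$core$eval(t, U, sys)
  if (!is.null(sys$markov)) {
    dU <- dU + closure_eval(sys$markov, closure_env_at(sys, U, t))
  }
  dY <- NULL
  if (!is.null(sys$nonmarkov)) {
    dU <- dU + Y
    Udel <- delayed_lookup(t - sys$nonmarkov$tau)
    dY <- nonmarkov_G(sys, U, t) - nonmarkov_G(sys, Udel, t - sys$nonmarkov$tau)
  }
  if (!is.null(sys$core$pinned)) dU[sys$core$pinned] <- 0
  list(dU = dU, dY = dY)
}

#' Solve the forward model
#'
#' Method-of-lines integration with adaptive time stepping (stiff BDF or
#' explicit embedded schemes per \code{sys$solver$method}). Delay systems
#' use the solver's continuously-updated history interpolant for the
#' delayed-state lookup.
#'
#' @param sys an \code{\link{npdde_system}}.
#' @param U0 initial state (nodes x states matrix or vector).
#' @param times increasing save times, \code{times[1]} is the initial time.
#' @return a \code{"pde_trajectory"} with snapshots and a piecewise cubic
#'   Hermite interpolant; access states with \code{\link{traj_state}}.
#' @export
solve_forward <- function(sys, U0, times) {
  U0 <- mat_state(vec_state(U0, sys$interleave), sys$n, sys$ns, sys$interleave)
  n_dof <- sys$n * sys$ns
  has_delay <- !is.null(sys$nonmarkov) && sys$nonmarkov$tau > 0 &&
    !is.null(sys$nonmarkov$cl)
  t0 <- times[1]
  if (any(diff(times) <= 0)) stop("save times must be strictly increasing")
  cap <- if (is.null(sys$solver$blowup_cap)) Inf else sys$solver$blowup_cap
  g_best_t <- -Inf; g_stale <- 0L
  guard <- function(t, y) {
    fail <- function(msg) {
      stop(structure(class = c("solver_failure", "error", "condition"),
                     list(message = sprintf(msg, t), call = NULL,
                          last_time = t)))
    }
    if (anyNA(y) || max(abs(y)) > cap) fail("solution blew up at t = %.6g")
    # step-size collapse: integration time stops advancing while the solver
    # keeps attempting steps (bounded grid-scale oscillation blow-ups)
    if (t > g_best_t + 1e-11) {
      g_best_t <<- t; g_stale <<- 0L
    } else {
      g_stale <<- g_stale + 1L
      if (g_stale > 500L) fail("integration stalled at t = %.6g")
    }
  }
  if (!has_delay) {
    fn <- function(t, y, p) {
      guard(t, y)
      U <- mat_state(y, sys$n, sys$ns, sys$interleave)
      r <- augmented_rhs(t, U, NULL, sys)
      list(vec_state(r$dU, sys$interleave))
    }
    args <- list(y = vec_state(U0, sys$interleave), times = times, func = fn,
                 parms = NULL, method = sys$solver$method,
                 rtol = sys$solver$rtol, atol = sys$solver$atol,
                 maxsteps = if (is.null(sys$solver$maxsteps)) 5000
                            else sys$solver$maxsteps)
    if (!is.null(sys$solver$hmax)) args$hmax <- sys$solver$hmax
    if (!is.null(sys$solver$bands) &&
        sys$solver$method %in% c("bdf", "lsoda", "lsode", "vode")) {
      args$jactype <- "bandint"
      args$bandup <- sys$solver$bands
      args$banddown <- sys$solver$bands
    }
    out <- do.call(deSolve::ode, args)
  } else {
    tau <- sys$nonmarkov$tau
    fn <- function(t, y, p) {
      guard(t, y)
      U <- mat_state(y[seq_len(n_dof)], sys$n, sys$ns, sys$interleave)
      Y <- mat_state(y[n_dof + seq_len(n_dof)], sys$n, sys$ns, sys$interleave)
      lookup <- function(td) {
        if (td <= t0) {
          sys$nonmarkov$history(td)
        } else {
          mat_state(deSolve::lagvalue(td, seq_len(n_dof)), sys$n, sys$ns,
                    sys$interleave)
        }
      }
      r <- augmented_rhs(t, U, Y, sys, lookup)
      list(c(vec_state(r$dU, sys$interleave), vec_state(r$dY, sys$interleave)))
    }
    y0 <- c(vec_state(U0, sys$interleave),
            vec_state(history_integral(sys, t0), sys$interleave))
    dm <- sys$solver$method
    if (!dm %in% c("lsoda", "lsode", "adams", "bdf", "vode", "impAdams")) {
      dm <- "adams"     # delay solves need the live-history (dede) family
    }
    dargs <- list(y = y0, times = times, func = fn, parms = NULL,
                  method = dm, rtol = sys$solver$rtol,
                  atol = sys$solver$atol, control = list(mxhist = 1e5))
    if (!is.null(sys$solver$hmax)) dargs$hmax <- sys$solver$hmax
    out <- do.call(deSolve::dede, dargs)
  }
  if (attr(out, "istate")[1] < 0 || nrow(out) < length(times)) {
    last_t <- out[nrow(out), 1]
    cond <- structure(class = c("solver_failure", "error", "condition"),
                      list(message = sprintf(
                        "forward solve failed at t = %.6g (requested %.6g)",
                        last_t, times[length(times)]),
                        call = NULL, last_time = last_t))
    stop(cond)
  }
  new_trajectory(out[, 1], out[, -1, drop = FALSE], sys)
}

new_trajectory <- function(times, Y, sys) {
  Y <- as.matrix(Y)
  nt <- length(times)
  # centred-difference knot slopes give a C1 piecewise-cubic Hermite
  # interpolant that reproduces the snapshots exactly at the knots
  slopes <- Y
  if (nt >= 3L) {
    dt_f <- diff(times)
    slopes[2:(nt - 1), ] <- (Y[3:nt, , drop = FALSE] - Y[1:(nt - 2), , drop = FALSE]) /
      (times[3:nt] - times[1:(nt - 2)])
    slopes[1, ] <- (Y[2, ] - Y[1, ]) / dt_f[1]
    slopes[nt, ] <- (Y[nt, ] - Y[nt - 1, ]) / dt_f[nt - 1]
  } else if (nt == 2L) {
    slopes[1, ] <- slopes[2, ] <- (Y[2, ] - Y[1, ]) / (times[2] - times[1])
  }
  structure(list(times = times, Y = Y, slopes = slopes,
                 n = sys$n, ns = sys$ns, interleave = sys$interleave,
                 state_names = sys$state_names),
            class = "pde_trajectory")
}

#' Evaluate the trajectory interpolant
#' @param traj a \code{"pde_trajectory"}.
#' @param t time inside the solved span.
#' @return full degrees-of-freedom vector at \code{t}.
#' @export
traj_interp <- function(traj, t) {
  tt <- traj$times
  nt <- length(tt)
  if (t < tt[1] - 1e-10 || t > tt[nt] + 1e-10) {
    stop(sprintf("interpolant queried at t = %.6g outside [%.6g, %.6g]",
                 t, tt[1], tt[nt]))
  }
  i <- findInterval(t, tt, rightmost.closed = TRUE)
  if (i >= nt) return(traj$Y[nt, ])
  if (t == tt[i]) return(traj$Y[i, ])
  h <- tt[i + 1] - tt[i]
  s <- (t - tt[i]) / h
  h00 <- (1 + 2 * s) * (1 - s)^2
  h10 <- s * (1 - s)^2
  h01 <- s^2 * (3 - 2 * s)
  h11 <- s^2 * (s - 1)
  h00 * traj$Y[i, ] + h10 * h * traj$slopes[i, ] +
    h01 * traj$Y[i + 1, ] + h11 * h * traj$slopes[i + 1, ]
}

#' State matrix at a time (delay/memory channels excluded)
#' @param traj a \code{"pde_trajectory"}.
#' @param t query time.
#' @return nodes x states matrix.
#' @export
traj_state <- function(traj, t) {
  v <- traj_interp(traj, t)
  mat_state(v[seq_len(traj$n * traj$ns)], traj$n, traj$ns, traj$interleave)
}

#' Bundle truth snapshots into a training dataset
#'
#' @param times snapshot times.
#' @param states list of state matrices (nodes x states), one per time, or a
#'   3-d array (nodes x states x times).
#' @param grid the grid the snapshots live on.
#' @return a \code{"closure_dataset"} with snapshot array and an interpolant
#'   (used to initialize training sub-intervals and as delay history).
#' @export
closure_dataset <- function(times, states, grid) {
  if (is.list(states)) {
    arr <- array(0, c(nrow(states[[1]]), ncol(states[[1]]), length(times)))
    for (i in seq_along(times)) arr[, , i] <- states[[i]]
  } else arr <- states
  ns <- dim(arr)[2]
  interleave <- ns > 1L
  Y <- t(apply(arr, 3, function(U) vec_state(U, interleave)))
  if (dim(arr)[3] == 1L) Y <- matrix(Y, nrow = 1L)
  fake_sys <- list(n = dim(arr)[1], ns = ns, interleave = interleave,
                   state_names = dimnames(arr)[[2]])
  tr <- new_trajectory(times, Y, fake_sys)
  structure(list(times = times, U = arr, traj = tr, grid = grid,
                 n = dim(arr)[1], ns = ns),
            class = "closure_dataset")
}

#' State matrix of a dataset at a time (via its interpolant)
#' @param data a \code{closure_dataset}.
#' @param t query time.
#' @return nodes x states matrix.
#' @export
dataset_state <- function(data, t) traj_state(data$traj, t)
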