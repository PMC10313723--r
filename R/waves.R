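# Nonlinear-wave testbeds.
#
# KdV-Burgers: truth is u_t = -6 u u_x - u_xxx with an exact two-soliton
# solution; the low-fidelity model keeps only weak advection u_t = -u u_x
# and the closure must discover the missing physics from a term library.
#
# Burgers: truth is the analytic viscous-shock solution of
# u_t = -u u_x + nu u_xx; the low-fidelity model is the same equation on a
# coarse grid with low-order schemes, and the closure must represent the
# leading truncation error.

#' Two-soliton parameters for the KdV-Burgers testbed
#' @param eta1,eta2 soliton scale parameters (amplitudes are 2*eta^2),
#'   \code{eta1 >= eta2 > 0}.
#' @param x1,x2 initial soliton centres.
#' @param L half-domain (domain is \code{[-L, L]}).
#' @param T_end evaluation horizon.
#' @return parameter list.
#' @export
soliton_params <- function(eta1 = 1.2, eta2 = 0.8, x1 = -6, x2 = -2,
                           L = 10, T_end = 1.5) {
  stopifnot(eta1 >= eta2, eta2 > 0)
  list(eta1 = eta1, eta2 = eta2, x1 = x1, x2 = x2, L = L, T_end = T_end)
}

#' Analytic two-soliton solution of the KdV equation
#'
#' Evaluates the exact bilinear (tau-function) two-soliton solution of
#' \code{u_t = -6 u u_x - u_xxx}: \code{u = 2 (log f)_xx} with
#' \code{f = 1 + E1 + E2 + A E1 E2}, \code{Ei = exp(2 theta_i)},
#' \code{theta_i = eta_i (x - x_i) - 4 eta_i^3 t} and interaction
#' coefficient \code{A = ((eta1-eta2)/(eta1+eta2))^2}. For well-separated
#' initial positions this places solitons of amplitude \code{2 eta_i^2} at
#' \code{x_i} at \code{t = 0}. Derivatives of \code{log f} are evaluated in
#' closed form with overflow-safe rescaling.
#'
#' @param x positions (vector).
#' @param t time (scalar).
#' @param p parameters from \code{\link{soliton_params}}.
#' @return u values at \code{(x, t)}.
#' @export
kdv_two_soliton <- function(x, t, p = soliton_params()) {
  e1 <- p$eta1; e2 <- p$eta2
  A <- ((e1 - e2) / (e1 + e2))^2
  th1 <- e1 * (x - p$x1) - 4 * e1^3 * t
  th2 <- e2 * (x - p$x2) - 4 * e2^3 * t
  # terms of f with log-scale bookkeeping: exponents 0, 2th1, 2th2, 2th1+2th2+logA
  ex <- cbind(0, 2 * th1, 2 * th2, 2 * th1 + 2 * th2 + log(A))
  m <- apply(ex, 1, max)
  T0 <- exp(-m); T1 <- exp(2 * th1 - m); T2 <- exp(2 * th2 - m)
  T12 <- exp(2 * th1 + 2 * th2 + log(A) - m)
  f <- T0 + T1 + T2 + T12
  fx <- 2 * e1 * T1 + 2 * e2 * T2 + 2 * (e1 + e2) * T12
  fxx <- 4 * e1^2 * T1 + 4 * e2^2 * T2 + 4 * (e1 + e2)^2 * T12
  2 * (fxx * f - fx^2) / f^2
}

#' Viscous-shock parameters for the Burgers testbed
#' @param Re Reynolds number (\code{nu = 1/Re}).
#' @param L domain length (domain is \code{[0, L]}).
#' @param T_end evaluation horizon.
#' @param Cs Smagorinsky constant for the eddy-viscosity baseline.
#' @return parameter list (includes \code{nu}, \code{t0 = exp(Re/8)}).
#' @export
burgers_params <- function(Re = 1000, L = 1.25, T_end = 8, Cs = 1.0) {
  list(Re = Re, nu = 1 / Re, t0 = exp(Re / 8), L = L, T_end = T_end, Cs = Cs)
}

#' Analytic solution of the Burgers equation
#'
#' \code{u(x,t) = (x/(t+1)) / (1 + sqrt((t+1)/t0) exp(Re x^2 / (4t+4)))}
#' with \code{t0 = exp(Re/8)}; at \code{t = 0} it reduces to the initial
#' hump and it satisfies \code{u(0,t) = 0} and \code{u_x -> 0} on the right.
#'
#' @param x positions.
#' @param t time (scalar).
#' @param p parameters from \code{\link{burgers_params}}.
#' @return u values.
#' @export
burgers_analytical <- function(x, t, p = burgers_params()) {
  # sqrt((t+1)/t0) = exp(log(t+1)/2 - Re/16); keep in log space for large Re
  lpre <- 0.5 * log(t + 1) - p$Re / 16
  (x / (t + 1)) / (1 + exp(lpre + p$Re * x^2 / (4 * t + 4)))
}

kdv_bcs <- function() {
  bc_spec(left = list(bc_dirichlet0()),
          right = list(bc_neumann0(), list(order = 2L, value = 0)))
}

burgers_bcs <- function(right = c("neumann", "dirichlet")) {
  right <- match.arg(right)
  bc_spec(left = list(bc_dirichlet0()),
          right = if (right == "neumann") list(bc_neumann0())
                  else list(bc_dirichlet0()))
}

# row-combined upwind matrix for the current wind field
upwind_matrix <- function(op, wind) {
  n <- length(wind)
  pos <- as.numeric(wind > 0); neg <- as.numeric(wind < 0)
  tie <- 1 - pos - neg
  Matrix::Diagonal(n, pos) %*% op$Dm + Matrix::Diagonal(n, neg) %*% op$Dp +
    Matrix::Diagonal(n, tie) %*% op$Dc
}

#' Build a wave-model core
#'
#' @param grid a \code{\link{grid1d}}.
#' @param kind one of \code{"kdv_true"} (full KdV-Burgers:
#'   \code{-6 u u_x - u_xxx}), \code{"kdv_lowfi"} (\code{-u u_x}),
#'   \code{"burgers"} (\code{-u u_x + nu u_xx}), \code{"burgers_trunc"}
#'   (Burgers plus the leading truncation-error term
#'   \code{-dx/2 u u_xx} as a fixed closure), \code{"burgers_smag"}
#'   (Burgers plus Smagorinsky eddy viscosity
#'   \code{(Cs dx)^2 |u_x|}).
#' @param params \code{\link{burgers_params}} for Burgers kinds.
#' @param right_bc right-edge boundary kind for Burgers ("neumann" or
#'   "dirichlet").
#' @return core list for \code{\link{npdde_system}}.
#' @export
wave_core <- function(grid, kind, params = NULL,
                      right_bc = c("neumann", "dirichlet")) {
  right_bc <- match.arg(right_bc)
  n <- grid$n
  if (kind %in% c("kdv_true", "kdv_lowfi")) {
    bcs <- kdv_bcs()
    up <- deriv_operator(grid, fd_scheme("upwind", 2L, 1L), bcs)
    d3 <- if (kind == "kdv_true")
      deriv_operator(grid, fd_scheme("central", 4L, 3L), bcs) else NULL
    adv_c <- if (kind == "kdv_true") 6 else 1
    pinned <- matrix(FALSE, n, 1L); pinned[1L, 1L] <- TRUE
    ev <- function(t, U, sys) {
      u <- U[, 1L]
      du <- -adv_c * u * apply_op(up, u, wind = u, t = t)
      if (!is.null(d3)) du <- du - apply_op(d3, u, t = t)
      matrix(du, n, 1L)
    }
    jt_parts <- function(sys) {
      parts <- list(
        list(D = NULL, s_in = 1L, s_out = 1L,
             coef = function(ctx) {
               u <- ctx$U[, 1L]
               -adv_c * apply_op(up, u, wind = u, t = ctx$t)
             }),
        list(D = up$Dm, s_in = 1L, s_out = 1L,
             coef = function(ctx) {
               u <- ctx$U[, 1L]; -adv_c * u * (u > 0)
             }),
        list(D = up$Dp, s_in = 1L, s_out = 1L,
             coef = function(ctx) {
               u <- ctx$U[, 1L]; -adv_c * u * (u < 0)
             }),
        list(D = up$Dc, s_in = 1L, s_out = 1L,
             coef = function(ctx) {
               u <- ctx$U[, 1L]; -adv_c * u * (u == 0)
             }))
      if (!is.null(d3)) {
        parts <- c(parts, list(list(D = d3$D, s_in = 1L, s_out = 1L,
                                    coef = function(ctx) rep(-1, ctx$n))))
      }
      parts
    }
    return(list(eval = ev, jt_parts = jt_parts, pinned = pinned, bcs = bcs,
                kind = kind))
  }
  if (!kind %in% c("burgers", "burgers_trunc", "burgers_smag")) {
    stop("unknown model kind: ", kind)
  }
  if (is.null(params)) stop("burgers kinds need params")
  bcs <- burgers_bcs(right_bc)
  up <- deriv_operator(grid, fd_scheme("upwind", 1L, 1L), bcs)
  d2 <- deriv_operator(grid, fd_scheme("central", 2L, 2L), bcs)
  d2f <- deriv_operator(grid, fd_scheme("central", 4L, 2L), bcs)
  d1f <- deriv_operator(grid, fd_scheme("central", 2L, 1L), bcs)
  nu <- params$nu
  pinned <- matrix(FALSE, n, 1L); pinned[1L, 1L] <- TRUE
  if (right_bc == "dirichlet") pinned[n, 1L] <- TRUE
  ev <- function(t, U, sys) {
    u <- U[, 1L]
    du <- -u * apply_op(up, u, wind = u, t = t) + nu * apply_op(d2, u, t = t)
    if (kind == "burgers_trunc") {
      du <- du - grid$dx / 2 * u * apply_op(d2f, u, t = t)
    } else if (kind == "burgers_smag") {
      ux <- apply_op(d1f, u, t = t)
      du <- du + apply_op(d1f, (params$Cs * grid$dx)^2 * abs(ux) * ux, t = t)
    }
    matrix(du, n, 1L)
  }
  jt_parts <- function(sys) {
    list(
      list(D = NULL, s_in = 1L, s_out = 1L,
           coef = function(ctx) {
             u <- ctx$U[, 1L]
             -apply_op(up, u, wind = u, t = ctx$t)
           }),
      list(D = up$Dm, s_in = 1L, s_out = 1L,
           coef = function(ctx) { u <- ctx$U[, 1L]; -u * (u > 0) }),
      list(D = up$Dp, s_in = 1L, s_out = 1L,
           coef = function(ctx) { u <- ctx$U[, 1L]; -u * (u < 0) }),
      list(D = up$Dc, s_in = 1L, s_out = 1L,
           coef = function(ctx) { u <- ctx$U[, 1L]; -u * (u == 0) }),
      list(D = d2$D, s_in = 1L, s_out = 1L,
           coef = function(ctx) rep(nu, ctx$n)))
  }
  list(eval = ev, jt_parts = if (kind == "burgers") jt_parts else NULL,
       pinned = pinned, bcs = bcs, kind = kind)
}

# conservative adjoint time-step heuristics (explicit backward RK4)
wave_adj_dt <- function(grid, kind, params = NULL, umax = 3) {
  dx <- grid$dx
  if (startsWith(kind, "kdv")) {
    rate <- 6 * umax * 3 / dx + if (kind == "kdv_true") 6 / dx^3 else 0
    return(min(0.5 / rate, 2 / (6 / dx^3 + 1)))
  }
  rate <- 3 * umax / dx + 4 * params$nu / dx^2 + 1
  0.8 / rate
}

#' KdV-Burgers term-discovery library
#'
#' Candidate terms \code{u_xx}, \code{u_xxx}, \code{u u_x}, \code{u^2 u_x};
#' derivatives are taken with free (boundary-one-sided) 4th-order central
#' stencils.
#' @return a \code{\link{function_library}}.
#' @export
lib_kdv <- function() {
  function_library(
    library_term("u_xx", function(e) env_d(e, 1L, 2L),
                 list(list(state = 1L, order = 2L, fn = function(e) rep(1, nrow(e$u))))),
    library_term("u_xxx", function(e) env_d(e, 1L, 3L),
                 list(list(state = 1L, order = 3L, fn = function(e) rep(1, nrow(e$u))))),
    library_term("u.u_x", function(e) e$u[, 1L] * env_d(e, 1L, 1L),
                 list(list(state = 1L, order = 0L, fn = function(e) env_d(e, 1L, 1L)),
                      list(state = 1L, order = 1L, fn = function(e) e$u[, 1L]))),
    library_term("u2.u_x", function(e) e$u[, 1L]^2 * env_d(e, 1L, 1L),
                 list(list(state = 1L, order = 0L, fn = function(e) 2 * e$u[, 1L] * env_d(e, 1L, 1L)),
                      list(state = 1L, order = 1L, fn = function(e) e$u[, 1L]^2))))
}

#' Burgers truncation-error library
#'
#' Second-degree combinations of \code{u}, \code{u_x}, \code{u_xx} scaled by
#' powers of \code{dx} for dimensional consistency: \code{dx (u_x)^2},
#' \code{dx^3 (u_xx)^2}, \code{dx^2 u_x u_xx}, \code{dx u u_xx}. The
#' advective \code{u u_x} (already in the model) and derivative-free
#' \code{u^2} are deliberately excluded.
#' @return a \code{\link{function_library}}.
#' @export
lib_burgers <- function() {
  function_library(
    library_term("dx.ux2",
                 function(e) e$params$dx * env_d(e, 1L, 1L)^2,
                 list(list(state = 1L, order = 1L,
                           fn = function(e) 2 * e$params$dx * env_d(e, 1L, 1L)))),
    library_term("dx3.uxx2",
                 function(e) e$params$dx^3 * env_d(e, 1L, 2L)^2,
                 list(list(state = 1L, order = 2L,
                           fn = function(e) 2 * e$params$dx^3 * env_d(e, 1L, 2L)))),
    library_term("dx2.ux.uxx",
                 function(e) e$params$dx^2 * env_d(e, 1L, 1L) * env_d(e, 1L, 2L),
                 list(list(state = 1L, order = 1L,
                           fn = function(e) e$params$dx^2 * env_d(e, 1L, 2L)),
                      list(state = 1L, order = 2L,
                           fn = function(e) e$params$dx^2 * env_d(e, 1L, 1L)))),
    library_term("dx.u.uxx",
                 function(e) e$params$dx * e$u[, 1L] * env_d(e, 1L, 2L),
                 list(list(state = 1L, order = 0L,
                           fn = function(e) e$params$dx * env_d(e, 1L, 2L)),
                      list(state = 1L, order = 2L,
                           fn = function(e) e$params$dx * e$u[, 1L]))))
}

#' Snapshot-averaged spatial RMSE error metrics
#'
#' \code{rmse = mean_i sqrt(mean_j delta_ij^2)}. \code{rmse_gt2pct} applies
#' the same formula restricted to grid points where
#' \code{|delta| >= 0.02 max|u_true|} (threshold from the global maximum of
#' the true field); snapshots with an empty mask contribute zero.
#'
#' @param pred,true matrices (times x nodes) or 3-d arrays (nodes x 1 x
#'   times) on matching grids/times.
#' @return list \code{(rmse, rmse_gt2pct)}.
#' @export
error_metrics <- function(pred, true) {
  if (length(dim(pred)) == 3L) pred <- t(apply(pred, 3L, identity))
  if (length(dim(true)) == 3L) true <- t(apply(true, 3L, identity))
  stopifnot(all(dim(pred) == dim(true)))
  delta <- pred - true
  thr <- 0.02 * max(abs(true))
  per_t <- sqrt(rowMeans(delta^2))
  per_t2 <- apply(delta, 1L, function(d) {
    m <- abs(d) >= thr
    if (!any(m)) 0 else sqrt(mean(d[m]^2))
  })
  list(rmse = mean(per_t), rmse_gt2pct = mean(per_t2))
}

#' Evaluate a Burgers closure over a grid of (Nx, Re) conditions
#'
#' Solves the closed model to \code{T_end} in each cell and reports the
#' masked RMSE against the analytic solution; solver blow-ups are recorded
#' as unconverged cells rather than raised.
#'
#' @param make_system function \code{(grid, params)} returning an
#'   \code{\link{npdde_system}} for one cell.
#' @param Nx_list,Re_list lattice of grid sizes and Reynolds numbers.
#' @param T_end evaluation horizon.
#' @param dt_save snapshot interval for the error metric.
#' @param L domain length.
#' @return data frame with columns Nx, Re, rmse, rmse_gt2pct, converged.
#' @export
generalization_sweep <- function(make_system, Nx_list, Re_list, T_end = 8,
                                 dt_save = 0.1, L = 1.25) {
  res <- expand.grid(Nx = Nx_list, Re = Re_list)
  res$rmse <- NA_real_; res$rmse_gt2pct <- NA_real_; res$converged <- FALSE
  times <- seq(0, T_end, by = dt_save)
  for (i in seq_len(nrow(res))) {
    p <- burgers_params(Re = res$Re[i], L = L, T_end = T_end)
    g <- grid1d(0, L, res$Nx[i])
    sys <- make_system(g, p)
    u0 <- burgers_analytical(g$x, 0, p)
    ok <- TRUE
    traj <- tryCatch(solve_forward(sys, u0, times), error = function(e) NULL)
    if (is.null(traj) || !all(is.finite(traj$Y)) || max(abs(traj$Y)) > 1e3) {
      ok <- FALSE
    }
    if (ok) {
      true <- t(vapply(times, function(t) burgers_analytical(g$x, t, p),
                       numeric(g$n)))
      em <- error_metrics(traj$Y[, seq_len(g$n), drop = FALSE], true)
      res$rmse[i] <- em$rmse
      res$rmse_gt2pct[i] <- em$rmse_gt2pct
      res$converged[i] <- TRUE
    }
    res$converged[i] <- ok
  }
  res
}
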