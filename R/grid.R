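#' Uniform node-centred 1-D grid
#'
#' Endpoint-inclusive uniform grid. The spacing \code{dx} is exposed to
#' closure models as a feature, so that learned closures can be
#' grid-resolution aware (e.g. truncation-error terms scale with powers of
#' \code{dx}).
#'
#' @param x_left,x_right domain endpoints (\code{x_right > x_left}).
#' @param n_points number of nodes including both endpoints (>= 2).
#' @return object of class \code{"grid1d"} with fields \code{x_left},
#'   \code{x_right}, \code{n}, \code{dx} and node coordinates \code{x}.
#' @export
grid1d <- function(x_left, x_right, n_points) {
  n_points <- as.integer(n_points)
  if (n_points < 2L) stop("n_points must be at least 2")
  if (!(x_right > x_left)) stop("x_right must exceed x_left")
  dx <- (x_right - x_left) / (n_points - 1L)
  structure(
    list(x_left = x_left, x_right = x_right, n = n_points, dx = dx,
         x = seq(x_left, x_right, length.out = n_points)),
    class = "grid1d")
}

#' Boundary-condition specification for one state variable
#'
#' Each side holds a list of conditions \code{list(order = k, value = g)}
#' where \code{k >= 0} is the derivative order (0 = Dirichlet, 1 = Neumann,
#' 2 = curvature, ...) and \code{g} is a constant or a function of time.
#' Ghost-cell values are produced by a boundary polynomial that interpolates
#' near-boundary interior nodes and satisfies every condition exactly.
#'
#' @param left,right lists of conditions; may be empty lists if a side of the
#'   operator never needs ghost values.
#' @return object of class \code{"bc_spec"}.
#' @export
bc_spec <- function(left = list(), right = list()) {
  chk <- function(side, nm) {
    for (cond in side) {
      if (is.null(cond$order) || cond$order < 0) {
        stop("each ", nm, " condition needs a derivative order >= 0")
      }
      if (is.null(cond$value)) stop("each ", nm, " condition needs a value")
    }
    ks <- vapply(side, function(c) as.integer(c$order), integer(1))
    if (anyDuplicated(ks)) stop("duplicate derivative orders in ", nm, " conditions")
    side
  }
  structure(list(left = chk(left, "left"), right = chk(right, "right")),
            class = "bc_spec")
}

bc_dirichlet0 <- function() list(order = 0L, value = 0)
bc_neumann0 <- function() list(order = 1L, value = 0)

# Ghost-extrapolation maps for one side.
#
# A polynomial of degree (m_int + n_bc - 1) is fitted through the m_int
# interior nodes nearest the boundary and constrained by the n_bc boundary
# conditions; it is then evaluated at the ghost nodes. The construction is
# affine in the interior values:  ghost = L %*% u_near + bvec(t).
# Basis is monomials in (x - x_b)/dx for conditioning.
ghost_side_map <- function(grid, conds, n_ghost, side) {
  n_bc <- length(conds)
  degree <- 5L                     # supports 4th-order stencils with <= 2 BCs
  m_int <- degree + 1L - n_bc
  # an order-0 condition already fixes the value at the boundary node, which
  # is itself a grid node: skip it in the interpolation set to stay full rank
  has_dirichlet <- any(vapply(conds, function(c) c$order == 0L, logical(1)))
  skip <- if (has_dirichlet) 1L else 0L
  if (m_int + skip > grid$n) stop("grid too small for ghost extrapolation")
  dx <- grid$dx
  if (side == "left") {
    xb <- grid$x_left
    int_idx <- skip + seq_len(m_int)
    ghost_s <- -(n_ghost:1)          # scaled offsets of ghosts
  } else {
    xb <- grid$x_right
    int_idx <- grid$n - skip - seq_len(m_int) + 1L
    ghost_s <- seq_len(n_ghost)
  }
  s_int <- (grid$x[int_idx] - xb) / dx
  # rows: n_bc condition rows then m_int interpolation rows
  A <- matrix(0, n_bc + m_int, degree + 1L)
  for (i in seq_len(n_bc)) {
    k <- as.integer(conds[[i]]$order)
    if (k > degree) stop("boundary condition derivative order too high")
    A[i, k + 1L] <- factorial(k) / dx^k      # P^(k)(xb) in original units
  }
  for (i in seq_len(m_int)) {
    A[n_bc + i, ] <- s_int[i]^(0:degree)
  }
  if (abs(det(A)) < .Machine$double.eps) stop("over-/under-determined boundary condition set")
  Ainv <- solve(A)
  V <- outer(ghost_s, 0:degree, `^`)         # evaluate at ghosts
  M <- V %*% Ainv                            # (n_ghost) x (n_bc + m_int)
  L <- M[, n_bc + seq_len(m_int), drop = FALSE]
  Mg <- M[, seq_len(n_bc), drop = FALSE]
  gvals <- function(t) {
    vapply(conds, function(cond) {
      v <- cond$value
      if (is.function(v)) v(t) else v
    }, numeric(1))
  }
  list(L = L, Mg = Mg, int_idx = int_idx, gvals = gvals, n_bc = n_bc)
}

#' Populate ghost layers from boundary conditions
#'
#' Returns the field extended by \code{n_ghost} ghost nodes on each side,
#' filled so that each boundary condition is reproduced to the accuracy of a
#' degree-5 boundary polynomial. Interior values are returned unmodified.
#' Idempotent on fields whose boundary polynomial already satisfies the
#' conditions.
#'
#' @param values field of length \code{grid$n}.
#' @param grid a \code{\link{grid1d}}.
#' @param bcs a \code{\link{bc_spec}}; both sides must carry at least one
#'   condition.
#' @param t time passed to time-dependent boundary values.
#' @param n_ghost number of ghost layers per side (default 3 supports
#'   4th-order stencils of third derivatives).
#' @return numeric vector of length \code{n + 2 n_ghost} with attribute
#'   \code{n_ghost}.
#' @export
apply_boundary_conditions <- function(values, grid, bcs, t = 0, n_ghost = 3L) {
  if (length(values) != grid$n) stop("field length must equal grid$n")
  if (!length(bcs$left) || !length(bcs$right)) {
    stop("both sides need at least one boundary condition to fill ghosts")
  }
  ml <- ghost_side_map(grid, bcs$left, n_ghost, "left")
  mr <- ghost_side_map(grid, bcs$right, n_ghost, "right")
  gl <- drop(ml$L %*% values[ml$int_idx]) + drop(ml$Mg %*% ml$gvals(t))
  gr <- drop(mr$L %*% values[mr$int_idx]) + drop(mr$Mg %*% mr$gvals(t))
  out <- c(gl, values, gr)
  attr(out, "n_ghost") <- n_ghost
  out
}

#' Finite-difference derivative of a grid field
#'
#' Computes the d-th spatial derivative with the requested scheme. When a
#' \code{bc_spec} is supplied, ghost layers are filled first and the interior
#' stencil is applied at every node; otherwise boundary-adjacent nodes fall
#' back to one-sided stencils of the same formal accuracy.
#'
#' @param values field of length \code{grid$n}.
#' @param grid a \code{\link{grid1d}}.
#' @param scheme an \code{\link{fd_scheme}}.
#' @param wind signed advecting velocity (scalar or field), required for
#'   upwind schemes; the stencil direction follows \code{sign(wind)} per node
#'   and ties fall back to a central difference of the same accuracy order
#'   (rounded up to the nearest even order).
#' @param bcs optional \code{\link{bc_spec}} for ghost-cell closure.
#' @param t time for time-dependent boundary values.
#' @return derivative field of length \code{grid$n}.
#' @export
fd_derivative <- function(values, grid, scheme, wind = NULL, bcs = NULL, t = 0) {
  if (length(values) != grid$n) stop("field length must equal grid$n")
  if (scheme$kind == "upwind" && is.null(wind)) stop("missing advecting velocity")
  op <- deriv_operator(grid, scheme, bcs)
  apply_op(op, values, wind = wind, t = t)
}
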