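# Sparse finite-difference operators.
#
# Two flavours are built:
#  * "free" operators know nothing about boundary conditions; interior nodes
#    use the requested (central/upwind) stencil and boundary-adjacent nodes
#    fall back to one-sided stencils of the same formal accuracy. These are
#    used for closure-model input derivatives.
#  * "bc" operators act on the ghost-extended field, with ghosts filled from
#    a bc_spec; the ghost fill is affine in the interior values, so the whole
#    operator is an affine map  D u + b(t)  with sparse D. The linear part
#    and its transpose are what the backward adjoint solve uses.

stencil_rows <- function(n, dx, d, accuracy, kind, bias = 0L, offset_base = 0L) {
  # triplets for rows 1..n of the stencil applied to a field indexed
  # 1..(n + 2*offset_base) where offset_base shifts column indices (ghosts).
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  if (kind == "central") {
    h <- central_halfwidth(d, accuracy)
    off <- -h:h
    w <- uniform_weights(off, d, dx)
    for (k in seq_along(off)) {
      ii <- c(ii, seq_len(n))
      jj <- c(jj, seq_len(n) + off[k] + offset_base)
      xx <- c(xx, rep(w[k], n))
    }
  } else {
    off <- upwind_offsets(accuracy, bias > 0L)
    w <- uniform_weights(off, d, dx)
    for (k in seq_along(off)) {
      ii <- c(ii, seq_len(n))
      jj <- c(jj, seq_len(n) + off[k] + offset_base)
      xx <- c(xx, rep(w[k], n))
    }
  }
  list(i = ii, j = jj, x = xx)
}

# free operator matrix with one-sided boundary rows
free_deriv_matrix <- function(grid, d, accuracy, kind = "central", bias = 0L) {
  n <- grid$n; dx <- grid$dx
  if (kind == "central") {
    h <- central_halfwidth(d, accuracy)
    off <- -h:h
  } else {
    off <- upwind_offsets(accuracy, bias > 0L)
  }
  npts_onesided <- d + max(accuracy, 2L)  # one-sided width for matching order
  if (npts_onesided > n) stop("grid too small")
  if (max(abs(off)) * 2L + 1L > n) stop("grid too small")
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  w <- uniform_weights(off, d, dx)
  for (i in seq_len(n)) {
    cols <- i + off
    if (all(cols >= 1L & cols <= n)) {
      ii <- c(ii, rep(i, length(off))); jj <- c(jj, cols); xx <- c(xx, w)
    } else {
      # one-sided stencil anchored inside the domain
      if (i - 1L < npts_onesided) cols1 <- seq_len(npts_onesided)
      else cols1 <- n - npts_onesided + seq_len(npts_onesided)
      w1 <- fornberg_weights(grid$x[i], grid$x[cols1], d)[, d + 1L]
      ii <- c(ii, rep(i, length(cols1))); jj <- c(jj, cols1); xx <- c(xx, w1)
    }
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n))
}

# ghost-extension map: ext = E %*% u + b(t), length n + 2*n_ghost
ghost_extension <- function(grid, bcs, n_ghost = 3L) {
  n <- grid$n
  ml <- ghost_side_map(grid, bcs$left, n_ghost, "left")
  mr <- ghost_side_map(grid, bcs$right, n_ghost, "right")
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  for (g in seq_len(n_ghost)) {
    ii <- c(ii, rep(g, length(ml$int_idx)))
    jj <- c(jj, ml$int_idx)
    xx <- c(xx, ml$L[g, ])
  }
  ii <- c(ii, n_ghost + seq_len(n)); jj <- c(jj, seq_len(n)); xx <- c(xx, rep(1, n))
  for (g in seq_len(n_ghost)) {
    ii <- c(ii, rep(n_ghost + n + g, length(mr$int_idx)))
    jj <- c(jj, mr$int_idx)
    xx <- c(xx, mr$L[g, ])
  }
  E <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n + 2L * n_ghost, n))
  # affine part: nonzero only for inhomogeneous boundary values
  const_g <- all(vapply(c(bcs$left, bcs$right),
                        function(cond) !is.function(cond$value), logical(1)))
  bvec <- function(t) {
    b <- numeric(n + 2L * n_ghost)
    b[seq_len(n_ghost)] <- drop(ml$Mg %*% ml$gvals(t))
    b[n_ghost + n + seq_len(n_ghost)] <- drop(mr$Mg %*% mr$gvals(t))
    b
  }
  b0 <- bvec(0)
  homogeneous <- const_g && all(b0 == 0)
  list(E = E, bvec = bvec, b0 = b0, homogeneous = homogeneous,
       const_g = const_g, n_ghost = n_ghost)
}

#' Build a derivative operator for repeated application
#'
#' @param grid a \code{\link{grid1d}}.
#' @param scheme an \code{\link{fd_scheme}}.
#' @param bcs optional \code{\link{bc_spec}}; when supplied the operator acts
#'   through ghost layers, otherwise one-sided boundary stencils are used.
#' @return object of class \code{"fd_op"} with \code{apply}/transpose support
#'   via \code{\link{apply_op}} and \code{\link{apply_opT}}.
#' @export
deriv_operator <- function(grid, scheme, bcs = NULL) {
  n <- grid$n; dx <- grid$dx
  d <- scheme$d; p <- scheme$accuracy
  if (is.null(bcs)) {
    if (scheme$kind == "central") {
      D <- free_deriv_matrix(grid, d, p, "central")
      op <- list(type = "free_central", D = D, Dt = Matrix::t(D))
    } else {
      Dm <- free_deriv_matrix(grid, d, p, "upwind", bias = 1L)
      Dp <- free_deriv_matrix(grid, d, p, "upwind", bias = -1L)
      pc <- if (p %% 2L == 0L) p else p + 1L
      Dc <- free_deriv_matrix(grid, d, pc, "central")
      op <- list(type = "free_upwind", Dm = Dm, Dp = Dp, Dc = Dc,
                 Dmt = Matrix::t(Dm), Dpt = Matrix::t(Dp), Dct = Matrix::t(Dc))
    }
  } else {
    ng <- 3L
    ext <- ghost_extension(grid, bcs, ng)
    mk <- function(kind, bias, acc) {
      tr <- stencil_rows(n, dx, d, acc, kind, bias, offset_base = ng)
      Matrix::sparseMatrix(i = tr$i, j = tr$j, x = tr$x,
                           dims = c(n, n + 2L * ng))
    }
    if (scheme$kind == "central") {
      h <- central_halfwidth(d, p)
      if (h > ng) stop("stencil wider than ghost layer")
      S <- mk("central", 0L, p)
      D <- S %*% ext$E
      op <- list(type = "bc_central", D = D, Dt = Matrix::t(D), S = S, ext = ext)
    } else {
      Sm <- mk("upwind", 1L, p)
      Sp <- mk("upwind", -1L, p)
      pc <- if (p %% 2L == 0L) p else p + 1L
      Sc <- mk("central", 0L, pc)
      Dm <- Sm %*% ext$E; Dp <- Sp %*% ext$E; Dc <- Sc %*% ext$E
      op <- list(type = "bc_upwind", Dm = Dm, Dp = Dp, Dc = Dc,
                 Dmt = Matrix::t(Dm), Dpt = Matrix::t(Dp), Dct = Matrix::t(Dc),
                 Sm = Sm, Sp = Sp, Sc = Sc, ext = ext)
    }
  }
  op$scheme <- scheme
  op$grid <- grid
  class(op) <- "fd_op"
  op
}

#' Apply a derivative operator to a field
#' @param op an \code{"fd_op"} from \code{\link{deriv_operator}}.
#' @param v field of length \code{grid$n}.
#' @param wind signed advecting velocity for upwind operators.
#' @param t time for time-dependent boundary values.
#' @return derivative field.
#' @export
apply_op <- function(op, v, wind = NULL, t = 0) {
  affine <- function(S) {
    if (is.null(op$ext) || op$ext$homogeneous) return(0)
    as.numeric(S %*% op$ext$bvec(t))
  }
  if (op$type %in% c("free_central", "bc_central")) {
    out <- as.numeric(op$D %*% v)
    if (op$type == "bc_central") out <- out + affine(op$S)
    return(out)
  }
  if (is.null(wind)) stop("missing advecting velocity")
  w <- rep_len(wind, length(v))
  pos <- w > 0; neg <- w < 0; tie <- !(pos | neg)
  out <- numeric(length(v))
  if (any(pos)) out[pos] <- as.numeric(op$Dm %*% v)[pos]
  if (any(neg)) out[neg] <- as.numeric(op$Dp %*% v)[neg]
  if (any(tie)) out[tie] <- as.numeric(op$Dc %*% v)[tie]
  if (op$type == "bc_upwind" && !op$ext$homogeneous) {
    if (any(pos)) out[pos] <- out[pos] + affine(op$Sm)[pos]
    if (any(neg)) out[neg] <- out[neg] + affine(op$Sp)[neg]
    if (any(tie)) out[tie] <- out[tie] + affine(op$Sc)[tie]
  }
  out
}

#' Apply the transpose of the linear part of a derivative operator
#'
#' Used by the backward adjoint solve: the integration-by-parts pattern of
#' the continuous adjoint equations is realized discretely as the exact
#' transpose of the forward spatial discretization (including the ghost-cell
#' boundary closure).
#'
#' @param op an \code{"fd_op"}.
#' @param w adjoint field of length \code{grid$n}.
#' @param wind signed advecting velocity used in the corresponding forward
#'   application (direction pattern is frozen).
#' @return transposed-operator image of \code{w}.
#' @export
apply_opT <- function(op, w, wind = NULL) {
  if (op$type %in% c("free_central", "bc_central")) {
    return(as.numeric(op$Dt %*% w))
  }
  if (is.null(wind)) stop("missing advecting velocity")
  wd <- rep_len(wind, length(w))
  pos <- wd > 0; neg <- wd < 0; tie <- !(pos | neg)
  out <- numeric(length(w))
  if (any(pos)) out <- out + as.numeric(op$Dmt %*% ifelse(pos, w, 0))
  if (any(neg)) out <- out + as.numeric(op$Dpt %*% ifelse(neg, w, 0))
  if (any(tie)) out <- out + as.numeric(op$Dct %*% ifelse(tie, w, 0))
  out
}
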