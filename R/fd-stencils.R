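#' Finite-difference weights on arbitrary nodes
#'
#' Computes weights of finite-difference approximations to derivatives of
#' order \code{0..m} at location \code{z} from samples at nodes \code{x},
#' using Fornberg's recursion. Exact for polynomials of degree
#' \code{length(x) - 1}.
#'
#' @param z evaluation point.
#' @param x stencil node coordinates (distinct).
#' @param m highest derivative order required (\code{m < length(x)}).
#' @return matrix \code{length(x) x (m+1)}; column \code{k+1} holds the
#'   weights of the k-th derivative.
#' @keywords internal
fornberg_weights <- function(z, x, m) {
  n <- length(x)
  stopifnot(m < n)
  w <- matrix(0, n, m + 1L)
  c1 <- 1
  c4 <- x[1] - z
  w[1, 1] <- 1
  for (i in 2:n) {
    mn <- min(i, m + 1L)
    c2 <- 1
    c5 <- c4
    c4 <- x[i] - z
    for (j in 1:(i - 1L)) {
      c3 <- x[i] - x[j]
      c2 <- c2 * c3
      if (j == i - 1L) {
        if (mn >= 2L) {
          for (k in mn:2L) {
            w[i, k] <- c1 * ((k - 1L) * w[i - 1L, k - 1L] - c5 * w[i - 1L, k]) / c2
          }
        }
        w[i, 1] <- -c1 * c5 * w[i - 1L, 1] / c2
      }
      if (mn >= 2L) {
        for (k in mn:2L) {
          w[j, k] <- (c4 * w[j, k] - (k - 1L) * w[j, k - 1L]) / c3
        }
      }
      w[j, 1] <- c4 * w[j, 1] / c3
    }
    c1 <- c2
  }
  w
}

#' Derivative scheme descriptor
#'
#' @param kind "central" or "upwind". Upwind schemes are only defined for the
#'   first derivative and require a signed advecting velocity at evaluation
#'   time to pick the stencil direction.
#' @param accuracy formal order of accuracy: 1, 2 or 4 (central supports 2
#'   and 4; upwind supports 1 and 2).
#' @param d derivative order, 1 to 3.
#' @return object of class \code{"fd_scheme"}.
#' @export
fd_scheme <- function(kind = c("central", "upwind"), accuracy = 2L, d = 1L) {
  kind <- match.arg(kind)
  accuracy <- as.integer(accuracy)
  d <- as.integer(d)
  if (!d %in% 1:3) stop("derivative order d must be 1, 2 or 3")
  if (kind == "central" && !accuracy %in% c(2L, 4L)) {
    stop("central schemes support accuracy 2 or 4")
  }
  if (kind == "upwind") {
    if (d != 1L) stop("upwind schemes are defined for the first derivative only")
    if (!accuracy %in% c(1L, 2L)) stop("upwind schemes support accuracy 1 or 2")
  }
  structure(list(kind = kind, accuracy = accuracy, d = d), class = "fd_scheme")
}

# stencil halfwidth of a central scheme
central_halfwidth <- function(d, accuracy) {
  as.integer(floor((d + 1L) / 2L) + accuracy / 2L - 1L)
}

# offsets (in nodes) for one direction of an upwind scheme; wind > 0 uses
# backward-biased nodes
upwind_offsets <- function(accuracy, positive_wind) {
  off <- if (accuracy == 1L) c(-1L, 0L) else c(-2L, -1L, 0L)
  if (positive_wind) off else -rev(off)
}

# weights for uniform-grid stencil at given integer offsets
uniform_weights <- function(offsets, d, dx) {
  fornberg_weights(0, offsets * dx, d)[, d + 1L]
}
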