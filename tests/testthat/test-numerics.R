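test_that("central schemes differentiate polynomials exactly", {
  g <- grid1d(-1, 1, 41)
  # 4th-order, 2nd derivative on x^2 is exact everywhere
  d2 <- fd_derivative(g$x^2, g, fd_scheme("central", 4L, 2L))
  expect_lt(max(abs(d2 - 2)), 1e-10)
  # p-th order scheme is exact on degree p + d - 1
  d1 <- fd_derivative(g$x^4, g, fd_scheme("central", 4L, 1L))
  expect_lt(max(abs(d1 - 4 * g$x^3)), 1e-9)
  # constants have zero derivative under every scheme
  for (d in 1:3) {
    expect_lt(max(abs(fd_derivative(rep(3.7, g$n), g,
                                    fd_scheme("central", 2L, d)))), 1e-9)
  }
  expect_lt(max(abs(fd_derivative(rep(1.5, 41), g,
                                  fd_scheme("upwind", 2L, 1L), wind = 1))),
            1e-9)
})

test_that("measured convergence order matches the nominal order", {
  err_at <- function(dx, scheme, fn, dfn) {
    g <- grid1d(0, 2, round(2 / dx) + 1L)
    max(abs(fd_derivative(fn(g$x), g, scheme) - dfn(g$x)))
  }
  cases <- list(
    list(s = fd_scheme("central", 4L, 1L), ord = 4),
    list(s = fd_scheme("central", 2L, 2L), ord = 2),
    list(s = fd_scheme("central", 4L, 3L), ord = 4))
  for (cs in cases) {
    e1 <- err_at(0.05, cs$s, sin, if (cs$s$d == 1L) cos
                 else if (cs$s$d == 2L) function(x) -sin(x)
                 else function(x) -cos(x))
    e2 <- err_at(0.025, cs$s, sin, if (cs$s$d == 1L) cos
                 else if (cs$s$d == 2L) function(x) -sin(x)
                 else function(x) -cos(x))
    measured <- log2(e1 / e2)
    expect_gt(measured, cs$ord - 0.2)
  }
})

test_that("upwind schemes demand an advecting velocity", {
  g <- grid1d(0, 1, 21)
  expect_error(fd_derivative(g$x, g, fd_scheme("upwind", 1L, 1L)),
               "advecting velocity")
})

test_that("ghost filling honours boundary conditions", {
  g <- grid1d(-10, 10, 201)
  # constant field under homogeneous Neumann: ghosts equal the constant
  bc_n <- bc_spec(left = list(bc_neumann0()), right = list(bc_neumann0()))
  ext <- apply_boundary_conditions(rep(3.3, g$n), g, bc_n)
  expect_lt(max(abs(ext - 3.3)), 1e-10)
  # zero Dirichlet at the left: reconstructed boundary value is zero
  bc_k <- bc_spec(left = list(bc_dirichlet0()),
                  right = list(bc_neumann0(), list(order = 2L, value = 0)))
  u <- sin(g$x + 10)                      # satisfies u(-L) = 0
  ext2 <- apply_boundary_conditions(u, g, bc_k)
  w0 <- fornberg_weights(-10, g$x_left + (-3:3) * g$dx, 0)[, 1]
  expect_lt(abs(sum(w0 * ext2[1:7])), 1e-8)
  # interior values are untouched
  expect_identical(ext2[4:204], u)
  # first/second derivative conditions on the right are forced toward zero
  # even when the field does not satisfy them
  uc <- cos(g$x - 10)                     # u_x(L) = 0 but u_xx(L) = -1
  ext3 <- apply_boundary_conditions(uc, g, bc_k)
  idx <- length(ext3) - 6:0
  wr <- fornberg_weights(10, g$x_right + (-3:3) * g$dx, 2)
  expect_lt(abs(sum(wr[, 2] * ext3[idx])), 1e-6)
  expect_lt(abs(sum(wr[, 3] * ext3[idx])), 1e-6)
})

test_that("ghost filling is idempotent on compatible fields", {
  g <- grid1d(0, 5, 101)
  bcs <- bc_spec(left = list(list(order = 1L, value = 1)),
                 right = list(list(order = 1L, value = 1)))
  u <- g$x + 2                            # slope-1 field satisfies the BCs
  e1 <- apply_boundary_conditions(u, g, bcs)
  # reconstruct interior from the extension, refill, compare ghosts
  e2 <- apply_boundary_conditions(e1[4:104], g, bcs)
  expect_lt(max(abs(e1 - e2)), 1e-9)
})

test_that("stencils wider than the grid raise an error", {
  g <- grid1d(0, 1, 4)
  expect_error(fd_derivative(g$x, g, fd_scheme("central", 4L, 3L)),
               "grid too small")
})
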