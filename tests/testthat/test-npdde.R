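# constant-output "kernel": a linear closure over a constant feature
const_kernel <- function(value) {
  lib <- function_library(
    library_term("one", function(e) rep(1, nrow(e$u)), list()))
  cl <- closure_linear(lib, n_raw = 1L)
  closure_set_w(cl, value)
  cl$prunable <- FALSE
  cl
}

# kernel equal to the evaluation time s (via the exogenous channel)
time_kernel <- function() {
  lib <- function_library(
    library_term("t", function(e) e$exo$tval, list()))
  cl <- closure_linear(lib, n_raw = 1L)
  closure_set_w(cl, 1)
  cl
}

simple_grid_sys <- function(nonmark, exo_fn = NULL) {
  g <- grid1d(0, 1, 8L)
  core <- list(eval = function(t, U, sys) 0 * U,
               jt_parts = function(sys) list(),
               pinned = NULL, bcs = NULL)
  npdde_system(g, "u", core, nonmarkov = nonmark, exo_fn = exo_fn,
               solver = list(method = "lsoda", rtol = 1e-9, atol = 1e-11))
}

test_that("history integral of the delay kernel", {
  # zero kernel: zero memory state
  sys0 <- simple_grid_sys(list(cl = const_kernel(0), tau = 0.5,
                               history = function(t) matrix(1, 8, 1)))
  expect_true(all(history_integral(sys0) == 0))
  # constant kernel c over tau = 0.5 integrates to 0.5 c
  sysc <- simple_grid_sys(list(cl = const_kernel(2), tau = 0.5,
                               history = function(t) matrix(1, 8, 1)))
  expect_equal(as.numeric(history_integral(sysc)), rep(1, 8),
               tolerance = 1e-12)
  # kernel equal to s over [-1, 0] integrates to -1/2
  syst <- simple_grid_sys(list(cl = time_kernel(), tau = 1,
                               history = function(t) matrix(1, 8, 1)),
                          exo_fn = function(t) list(tval = rep(t, 8)))
  expect_equal(as.numeric(history_integral(syst)), rep(-0.5, 8),
               tolerance = 1e-10)
})

test_that("augmented system degenerates correctly", {
  fx <- kdv_test_system(n_x = 64L)
  u0 <- kdv_two_soliton(fx$grid$x, 0)
  # closure-free limit: RHS equals the pure low-fidelity model
  r <- augmented_rhs(0, matrix(u0, 64, 1), NULL, fx$sys)
  direct <- fx$sys$core$eval(0, matrix(u0, 64, 1), fx$sys)
  direct[fx$sys$core$pinned] <- 0
  expect_equal(r$dU, direct, tolerance = 1e-14)
  expect_null(r$dY)
  # constant kernel: dY = D(t) - D(t - tau) = 0, memory stays at y0
  g <- grid1d(0, 1, 8L)
  sysc <- simple_grid_sys(list(cl = const_kernel(3), tau = 0.4,
                               history = function(t) matrix(0, 8, 1)))
  r2 <- augmented_rhs(1, matrix(0, 8, 1), matrix(1.2, 8, 1), sysc,
                      delayed_lookup = function(t) matrix(0, 8, 1))
  expect_true(all(abs(r2$dY) < 1e-14))
  expect_equal(r2$dU, matrix(1.2, 8, 1))
})

test_that("memory state is inert when the delay kernel is zero", {
  # tau > 0 with a zero kernel must be snapshot-identical to tau = 0, and
  # independent of the history function
  p <- soliton_params()
  g <- grid1d(-p$L, p$L, 96L)
  u0 <- kdv_two_soliton(g$x, 0)
  times <- seq(0, 0.2, by = 0.05)
  mk <- function(nonmark) {
    npdde_system(g, "u", wave_core(g, "kdv_lowfi"), nonmarkov = nonmark,
                 solver = list(method = "lsoda", bands = 6L,
                               rtol = 1e-8, atol = 1e-10))
  }
  base <- solve_forward(mk(NULL), u0, times)
  for (hist in list(function(t) matrix(0, g$n, 1),
                    function(t) matrix(sin(g$x), g$n, 1))) {
    sysd <- mk(list(cl = const_kernel(0), tau = 0.07, history = hist))
    trajd <- solve_forward(sysd, u0, times)
    expect_equal(trajd$Y[, seq_len(g$n)], base$Y, tolerance = 1e-7)
  }
})

test_that("the trajectory interpolant reproduces its knots exactly", {
  fx <- kdv_test_system(n_x = 96L)
  times <- seq(0, 0.1, by = 0.02)
  traj <- solve_forward(fx$sys, kdv_two_soliton(fx$grid$x, 0), times)
  for (i in seq_along(times)) {
    expect_identical(traj_interp(traj, times[i]), traj$Y[i, ])
  }
  expect_error(traj_interp(traj, 0.2), "outside")
})

test_that("halving solver tolerances leaves snapshots nearly unchanged", {
  loose <- kdv_test_system(n_x = 128L, weights = c(0, -1, -5, 0),
                           rtol = 1e-6, atol = 1e-8)
  tight <- kdv_test_system(n_x = 128L, weights = c(0, -1, -5, 0),
                           rtol = 1e-8, atol = 1e-10)
  u0 <- kdv_two_soliton(loose$grid$x, 0)
  times <- seq(0, 0.3, by = 0.1)
  y1 <- solve_forward(loose$sys, u0, times)$Y
  y2 <- solve_forward(tight$sys, u0, times)$Y
  expect_lt(max(abs(y1 - y2)), 1e-4)
})

test_that("blown-up solves raise a structured failure with the last time", {
  fx <- kdv_test_system(n_x = 200L, weights = c(-0.5, 0, 0, 0))
  err <- tryCatch(
    suppressWarnings(solve_forward(fx$sys, kdv_two_soliton(fx$grid$x, 0),
                                   seq(0, 0.5, by = 0.05))),
    solver_failure = function(e) e)
  expect_s3_class(err, "solver_failure")
  expect_true(is.finite(err$last_time))
})
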