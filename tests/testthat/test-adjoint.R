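test_that("zero data misfit yields identically zero adjoint fields", {
  fx <- kdv_test_system(n_x = 96L, weights = c(0, -0.5, -2, 0))
  u0 <- kdv_two_soliton(fx$grid$x, 0.2)
  times <- seq(0.2, 0.26, by = 0.02)
  traj <- solve_forward(fx$sys, u0, times)
  # data equal to the prediction itself
  arr <- array(t(traj$Y), c(fx$grid$n, 1L, length(times)))
  dat <- closure_dataset(times, arr, fx$grid)
  adj <- solve_adjoint(fx$sys, traj, dat, loss_spec("mae"),
                       t0 = 0.2, t1 = 0.26)
  expect_true(all(adj$lambda == 0))
  grads <- assemble_gradients(fx$sys, traj, dat, loss_spec("mae"),
                              t0 = 0.2, t1 = 0.26)
  expect_true(all(grads$markov == 0))
})

test_that("terminal condition holds and gradients are linear in the adjoint", {
  fx <- kdv_test_system(n_x = 96L, weights = c(0, -0.5, -2, 0))
  tt <- seq(0.2, 0.3, by = 0.02)
  dat <- kdv_test_dataset(fx$grid, tt[-1])
  traj <- solve_forward(fx$sys, kdv_two_soliton(fx$grid$x, 0.2), tt)
  adj <- solve_adjoint(fx$sys, traj, dat, loss_spec("mae"))
  nt <- length(adj$times)
  expect_equal(adj$times[nt], 0.3)
  expect_true(all(adj$lambda[nt, ] == 0))   # lambda(T) = 0
  expect_gt(max(abs(adj$lambda[1, ])), 0)   # sources accumulated backward
})

test_that("memory adjoint equals the time integral of the state adjoint when the kernel is inert", {
  # with D_NN == 0 the memory equation gives mu(t) = int_t^T lambda ds
  fx <- oa_test_delay_system(hidden = c(4L), init_scale = 0)
  agg <- fx$agg
  U0 <- dataset_state(agg, 2)
  tgrid <- seq(2, 4, by = 0.5)
  traj <- solve_forward(fx$sys, U0, tgrid)
  spec <- loss_spec("scaled_sqrt", sigma = c(1, 0.25, 1, 2, 0.1))
  adj <- solve_adjoint(fx$sys, traj, agg, spec, t0 = 2, t1 = 4)
  # trapezoid quadrature of the stored lambda from t to T
  nt <- length(adj$times)
  dtv <- diff(adj$times)
  k <- which.min(abs(adj$times - 3))
  mu_quad <- colSums((adj$lambda[k:(nt - 1), , drop = FALSE] +
                        adj$lambda[(k + 1):nt, , drop = FALSE]) / 2 *
                       dtv[k:(nt - 1)])
  expect_equal(as.numeric(adj$mu[k, ]), as.numeric(mu_quad),
               tolerance = 1e-2)
})

test_that("adjoint gradients match finite differences for a small linear closure", {
  set.seed(7)
  fx <- kdv_test_system(n_x = 200L, weights = c(-0.05, -0.5, -2, -0.3),
                        rtol = 1e-9, atol = 1e-11, adj_dt = 1e-4)
  tt <- seq(0.01, 1, by = 0.01)
  dat <- kdv_test_dataset(fx$grid, tt)
  gc1 <- gradient_check(fx$sys, dat, loss_spec("mae"),
                        kdv_two_soliton(fx$grid$x, 0.30), 0.30, 0.33,
                        n_sample = 4L)
  expect_lt(gc1$max_rel_err, 1e-3)
})

test_that("adjoint gradients match finite differences through the delay kernel", {
  fx <- oa_test_delay_system(seed = 5L, hidden = c(6L, 6L), init_scale = 0.3)
  closure_set_w(fx$cls$markov, c(0.01, -0.02, 0.005, 0.001))
  spec <- loss_spec("scaled_sqrt", sigma = c(1, 0.25, 1, 2, 0.1))
  set.seed(9)
  gc1 <- gradient_check(fx$sys, fx$agg, spec, dataset_state(fx$agg, 3),
                        3, 5, n_sample = 6L)
  expect_lt(gc1$max_rel_err, 1e-2)
})

test_that("loss examples evaluate as defined", {
  g <- grid1d(0, 2, 21L)
  times <- c(0.5, 1)
  U <- array(1.5, c(21, 1, 2))
  dat <- closure_dataset(times, U, g)
  fake_sys <- list(n = 21L, ns = 1L, interleave = FALSE, state_names = "u")
  traj <- neuralclosure:::new_trajectory(times, matrix(1.5, 2, 21), fake_sys)
  expect_equal(loss_eval(traj, dat, loss_spec("mae")), 0)
  # constant offset e gives MAE e
  traj2 <- neuralclosure:::new_trajectory(times, matrix(1.5 + 0.2, 2, 21),
                                          fake_sys)
  expect_equal(loss_eval(traj2, dat, loss_spec("mae")), 0.2,
               tolerance = 1e-12)
  # single state, sigma 1, scaled kind, uniform error e -> sqrt(e)
  expect_equal(loss_eval(traj2, dat, loss_spec("scaled_sqrt", sigma = 1)),
               sqrt(0.2), tolerance = 1e-6)
})
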