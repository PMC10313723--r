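test_that("the two-soliton solution satisfies the KdV-Burgers equation", {
  p <- soliton_params()
  resid_norm <- function(dx) {
    x <- seq(-10, 10, by = dx)
    t <- 0.37; dt <- 1e-6
    u <- kdv_two_soliton(x, t, p)
    ut <- (kdv_two_soliton(x, t + dt, p) - kdv_two_soliton(x, t - dt, p)) /
      (2 * dt)
    g <- grid1d(-10, 10, length(x))
    ux <- fd_derivative(u, g, fd_scheme("central", 4L, 1L))
    uxxx <- fd_derivative(u, g, fd_scheme("central", 4L, 3L))
    interior <- 10:(length(x) - 10)
    max(abs(ut + 6 * u * ux + uxxx)[interior])
  }
  r1 <- resid_norm(0.01)
  r2 <- resid_norm(0.005)
  expect_lt(r2, r1 / 4)            # residual vanishes under refinement
  expect_lt(r2, 1e-2)
  # soliton amplitudes and asymptotics at t = 0
  x <- seq(-10, 10, by = 1e-3)
  expect_equal(max(kdv_two_soliton(x, 0, p)), 2 * p$eta1^2,
               tolerance = 2e-3)
  expect_lt(abs(kdv_two_soliton(-10, 0, p)), 1e-2)
  expect_lt(abs(kdv_two_soliton(10, 0, p)), 1e-2)
  expect_lt(abs(kdv_two_soliton(30, 0, p)), 1e-10)
})

test_that("the analytic shock solution satisfies the Burgers equation", {
  p <- burgers_params(Re = 200)
  # boundary and initial identities
  expect_equal(burgers_analytical(0, 1.3, p), 0)
  x <- seq(0, p$L, by = 0.005)
  ic <- x / (1 + sqrt(1 / p$t0) * exp(p$Re * x^2 / 4))
  expect_equal(burgers_analytical(x, 0, p), ic, tolerance = 1e-12)
  resid_norm <- function(dx) {
    x <- seq(0, p$L, by = dx)
    t <- 1.0; dt <- 1e-6
    u <- burgers_analytical(x, t, p)
    ut <- (burgers_analytical(x, t + dt, p) -
             burgers_analytical(x, t - dt, p)) / (2 * dt)
    g <- grid1d(0, p$L, length(x))
    ux <- fd_derivative(u, g, fd_scheme("central", 4L, 1L))
    uxx <- fd_derivative(u, g, fd_scheme("central", 4L, 2L))
    interior <- 5:(length(x) - 5)
    max(abs(ut + u * ux - p$nu * uxx)[interior])
  }
  expect_lt(resid_norm(0.0025), resid_norm(0.005) / 4)
})

test_that("wave model cores implement the prescribed terms", {
  p <- soliton_params()
  g <- grid1d(-p$L, p$L, 128L)
  u <- kdv_two_soliton(g$x, 0.1)
  U <- matrix(u, g$n, 1L)
  core_t <- wave_core(g, "kdv_true")
  core_l <- wave_core(g, "kdv_lowfi")
  # difference of true and low-fidelity tendencies = -5 u u_x - u_xxx in
  # the respective discretizations
  up <- deriv_operator(g, fd_scheme("upwind", 2L, 1L), neuralclosure:::kdv_bcs())
  d3 <- deriv_operator(g, fd_scheme("central", 4L, 3L), neuralclosure:::kdv_bcs())
  expected <- -5 * u * apply_op(up, u, wind = u) - apply_op(d3, u)
  got <- core_t$eval(0, U, NULL) - core_l$eval(0, U, NULL)
  expect_equal(as.numeric(got), expected, tolerance = 1e-12)

  # truncation closure adds -dx/2 u u_xx
  pb <- burgers_params(Re = 100)
  gb <- grid1d(0, pb$L, 64L)
  ub <- burgers_analytical(gb$x, 0.5, pb)
  Ub <- matrix(ub, gb$n, 1L)
  c0 <- wave_core(gb, "burgers", pb)
  ct <- wave_core(gb, "burgers_trunc", pb)
  d2f <- deriv_operator(gb, fd_scheme("central", 4L, 2L),
                        neuralclosure:::burgers_bcs())
  diff_t <- ct$eval(0, Ub, NULL) - c0$eval(0, Ub, NULL)
  expect_equal(as.numeric(diff_t), -gb$dx / 2 * ub * apply_op(d2f, ub),
               tolerance = 1e-12)

  # Smagorinsky eddy term vanishes on constant-slope fields
  cs <- wave_core(gb, "burgers_smag", pb)
  Us <- matrix(0.3 * gb$x, gb$n, 1L)
  diff_s <- cs$eval(0, Us, NULL) - c0$eval(0, Us, NULL)
  expect_lt(max(abs(diff_s[4:(gb$n - 4)])), 1e-10)
})

test_that("error metrics match their definition and a brute-force oracle", {
  set.seed(11)
  true <- matrix(rnorm(5 * 40), 5, 40)
  expect_equal(error_metrics(true, true), list(rmse = 0, rmse_gt2pct = 0))
  # uniform error above threshold appears identically in both metrics
  em <- error_metrics(true + 0.5, true)
  expect_equal(em$rmse, 0.5, tolerance = 1e-12)
  expect_equal(em$rmse_gt2pct, 0.5, tolerance = 1e-12)
  # mixed field: compare against a direct masked computation
  delta <- matrix(rnorm(5 * 40, sd = 0.05), 5, 40)
  delta[, 1:20] <- delta[, 1:20] / 100
  pred <- true + delta
  em2 <- error_metrics(pred, true)
  thr <- 0.02 * max(abs(true))
  oracle <- mean(apply(delta, 1, function(d) {
    m <- abs(d) >= thr
    if (!any(m)) 0 else sqrt(mean(d[m]^2))
  }))
  expect_equal(em2$rmse_gt2pct, oracle, tolerance = 1e-12)
  expect_gte(em2$rmse_gt2pct, 0)
})

test_that("learned closures are affine-equivariant (node-local)", {
  # shifting the spatial coordinate leaves node-wise closure outputs
  # unchanged: features depend only on local values and derivatives
  set.seed(12)
  cl <- closure_linear(lib_kdv(), n_raw = 1L)
  closure_set_w(cl, rnorm(4))
  p <- soliton_params()
  mkenv <- function(shift) {
    g <- grid1d(-p$L + shift, p$L + shift, 128L)
    sys <- npdde_system(g, "u", wave_core(g, "kdv_lowfi"), markov = cl)
    u <- kdv_two_soliton(g$x - shift, 0.2)
    neuralclosure:::closure_env_at(sys, matrix(u, g$n, 1L), 0)
  }
  o1 <- closure_eval(cl, mkenv(0))
  o2 <- closure_eval(cl, mkenv(2.5))
  expect_equal(o1, o2, tolerance = 1e-10)
})
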