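test_that("forcing and profiles match their closed forms", {
  ph <- oa_physics(); pp <- oa_params()
  for (t in c(0, 120, 300)) {
    fp0 <- forcing_and_profiles(0, t, ph, pp)
    fpb <- forcing_and_profiles(ph$D_z, t, ph, pp)
    expect_equal(fp0$K_z, ph$K_z0, tolerance = 1e-12)
    expect_equal(fpb$K_z, ph$K_zb, tolerance = 1e-12)
    expect_equal(fp0$I, ph$I0(t), tolerance = 1e-12)
  }
  # alkalinity-salinity relation: printed value at S = 30 and branch
  # continuity at the 32.34 PSU breakpoint
  expect_equal((198.10 + 61.75 * 30) / 1000, 2.05060)
  lo <- (198.10 + 61.75 * 32.34) / 1000
  hi <- (744.41 + 44.86 * 32.34) / 1000
  expect_equal(lo, 2.195095, tolerance = 1e-6)
  expect_equal(hi, 2.195182, tolerance = 1e-6)
  expect_lt(abs(hi - lo), 1e-4)
})

test_that("reaction terms: kinetics, conservation, mortality differences", {
  pp <- oa_params()
  set.seed(21)
  n <- 12
  U <- matrix(abs(rnorm(6 * n, mean = 2)), n, 6L)
  I <- runif(n, 10, 300)
  # Michaelis-Menten midpoint
  U1 <- U; U1[, 1] <- pp$K_N
  R <- biogeochem_rhs(U1, I, pp, "npzd_oa", "quadratic")
  fN <- U1[, 1] / (U1[, 1] + pp$K_N)
  expect_equal(fN, rep(0.5, n))
  # total biomass conservation for both mortality laws
  for (mk in c("linear", "quadratic")) {
    Rm <- biogeochem_rhs(U, I, pp, "npzd_oa", mk)
    expect_lt(max(abs(rowSums(Rm[, 1:4]))), 1e-13)
  }
  # quadratic-minus-linear mortality pattern, with the printed coefficients
  Rq <- biogeochem_rhs(U, I, pp, "npzd_oa", "quadratic")
  Rl <- biogeochem_rhs(U, I, pp, "npzd_oa", "linear")
  dd <- Rq - Rl
  z2 <- U[, 3]^2
  expect_equal(dd[, 3], -0.02998 * z2, tolerance = 1e-6)
  expect_equal(dd[, 4], +0.02998 * z2, tolerance = 1e-6)
  expect_equal(dd[, 5], -0.05621 * z2, tolerance = 1e-3)
  expect_lt(max(abs(dd[, c(1, 2, 6)])), 1e-13)
})

test_that("column operator: decoupling, uniform states, conservation", {
  pp <- oa_params(); ph <- oa_physics()
  g <- grid1d(0, ph$D_z, ph$N_z)
  # uniform-in-depth state: diffusion contributes nothing
  core <- oa_core(g, pp, ph, "npzd_oa", "quadratic")
  U <- matrix(rep(c(3, 1, 0.5, 0.2, 20, 2.2), each = g$n), g$n, 6L)
  dU <- core$eval(10, U, NULL)
  R <- biogeochem_rhs(U, core$irr(10), pp, "npzd_oa", "quadratic")
  expect_equal(dU, R, tolerance = 1e-12)
  # pure diffusion (all rates zero) conserves the depth integral
  pp0 <- oa_params(mu_max = 0, g_max = 0, m_P = 0, m_Z = 0, eps_remin = 0,
                   gamma_c = 0)
  sys0 <- oa_system(g, pp0, ph, "npzd_oa", "quadratic")
  set.seed(22)
  U0 <- matrix(abs(rnorm(6 * g$n, mean = 3)), g$n, 6L)
  traj <- solve_forward(sys0, U0, c(0, 15, 30))
  tot0 <- colSums(traj_state(traj, 0))
  tot1 <- colSums(traj_state(traj, 30))
  expect_equal(tot1, tot0, tolerance = 1e-6)
})

test_that("spin-up conserves biomass and approaches a reaction equilibrium", {
  pp <- oa_params(); ph <- oa_physics()
  g <- grid1d(0, ph$D_z, ph$N_z)
  U30 <- suppressWarnings(spinup_init(g, pp, ph, days = 30))
  expect_lt(max(abs(rowSums(U30[, 1:4]) - ph$T_bio(g$x))), 1e-9)
  expect_true(all(U30[, 2] > 0) && all(U30[, 3] > 0))
  # a longer spin-up reaches the equilibrium tolerance without warning
  expect_no_warning(spinup_init(g, pp, ph, days = 6000, tol = 1e-6))
})

test_that("the carbonate system does not feed back on the biology", {
  pp <- oa_params(); ph <- oa_physics()
  g <- grid1d(0, ph$D_z, ph$N_z)
  U0 <- suppressWarnings(spinup_init(g, pp, ph, days = 30))
  # fixed-step integration so trajectories are bitwise comparable
  sys <- oa_system(g, pp, ph, "npzd_oa", "quadratic",
                   solver = list(method = "rk4", hmax = NULL))
  times <- seq(0, 5, by = 0.05)
  t1 <- solve_forward(sys, U0, times)
  U0p <- U0
  U0p[, 5] <- U0p[, 5] + 500
  U0p[, 6] <- U0p[, 6] * 1.7
  t2 <- solve_forward(sys, U0p, times)
  bio_cols <- as.numeric(vapply(1:4, function(s) {
    if (sys$interleave) (seq_len(g$n) - 1L) * 6L + s else integer(0)
  }, numeric(g$n)))
  expect_identical(t1$Y[, bio_cols], t2$Y[, bio_cols])
})

test_that("closed high-fidelity column conserves depth-integrated biomass", {
  pp <- oa_params(); ph <- oa_physics()
  g <- grid1d(0, ph$D_z, ph$N_z)
  U0 <- suppressWarnings(spinup_init(g, pp, ph, days = 30))
  sys <- oa_system(g, pp, ph, "npzd_oa", "quadratic",
                   solver = list(rtol = 1e-8, atol = 1e-10))
  times <- seq(0, 40, by = 5)
  traj <- solve_forward(sys, U0, times)
  tot <- vapply(times, function(t) sum(rowSums(traj_state(traj, t)[, 1:4])),
                numeric(1))
  expect_lt(max(abs(tot - tot[1])) / tot[1], 1e-5)
})
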