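make_env <- function(u, d1 = NULL, d2 = NULL, d3 = NULL, dx = 0.1) {
  n <- length(u)
  list(u = matrix(u, n, 1L),
       d = list(list(d1, d2, d3)),
       params = list(dx = dx), exo = list(),
       opT = function(order, v) v)
}

test_that("library features evaluate node-wise", {
  env <- make_env(u = 2, d1 = 3, d2 = 4, d3 = 5)
  FT <- build_features(env, lib_kdv())
  expect_equal(as.numeric(FT), c(4, 5, 2 * 3, 4 * 3))
  # dimensional scalings with powers of dx in the shock library
  env2 <- make_env(u = 1, d1 = 2, d2 = 4, dx = 0.1)
  FB <- build_features(env2, lib_burgers())
  expect_equal(as.numeric(FB),
               c(0.1 * 4, 0.1^3 * 16, 0.1^2 * 8, 0.1 * 4),
               tolerance = 1e-12)
  expect_equal(as.numeric(FB), c(0.4, 0.016, 0.08, 0.4), tolerance = 1e-12)
})

test_that("mortality library reproduces the candidate laws at Z = 1", {
  lib <- neuralclosure:::lib_mortality(1L)
  env <- list(u = matrix(1, 1, 1))
  FT <- build_features(env, lib)
  expect_equal(as.numeric(FT), c(1, 1, 0.5, exp(1)))
})

test_that("missing derivative inputs are reported by feature name", {
  env <- make_env(u = 2)          # no derivatives supplied
  expect_error(build_features(env, lib_kdv()), "u_xx")
})

test_that("linear closures are linear in their weights", {
  set.seed(1)
  n <- 17
  env <- make_env(u = rnorm(n), d1 = rnorm(n), d2 = rnorm(n), d3 = rnorm(n))
  cl <- closure_linear(lib_kdv(), n_raw = 1L)
  w1 <- rnorm(4); w2 <- rnorm(4); a <- 0.7; b <- -1.3
  closure_set_w(cl, w1); o1 <- closure_eval(cl, env)
  closure_set_w(cl, w2); o2 <- closure_eval(cl, env)
  closure_set_w(cl, a * w1 + b * w2)
  expect_equal(closure_eval(cl, env), a * o1 + b * o2, tolerance = 1e-12)
  # explicit example: weights (-5, -1) on (u u_x, u_xxx)
  closure_set_w(cl, c(0, -1, -5, 0))
  expect_equal(as.numeric(closure_eval(cl, env)),
               -5 * env$u[, 1] * env$d[[1]][[1]] - env$d[[1]][[3]],
               tolerance = 1e-12)
  # all weights zero: identically zero contribution
  closure_set_w(cl, rep(0, 4))
  expect_true(all(closure_eval(cl, env) == 0))
})

test_that("gated deep closures vanish exactly where the gate does", {
  set.seed(2)
  cl <- closure_deep(list(list(kind = "state", state = 1L)),
                     hidden = c(8L), n_raw = 1L, gate_state = 1L,
                     init_scale = 0.5)
  u <- c(0, 0.5, -1, 0, 2)
  env <- list(u = matrix(u, 5, 1L), d = NULL, params = list(), exo = list())
  out <- closure_eval(cl, env)
  expect_identical(out[u == 0], c(0, 0))
  expect_true(all(out[u != 0] != 0))
  # zero weights give the zero closure even ungated
  cl0 <- closure_deep(list(list(kind = "state", state = 1L)),
                      hidden = c(8L), n_raw = 1L, init_scale = 0)
  expect_true(all(closure_eval(cl0, env) == 0))
})

test_that("conservation-constrained closures balance biomass exactly", {
  set.seed(3)
  params <- oa_params()
  cls <- oa_closure_builder("2a", params)
  closure_set_w(cls$markov, rnorm(12))
  n <- 20
  env <- list(u = matrix(abs(rnorm(n * 6)), n, 6L), d = NULL,
              params = list(), exo = list())
  out <- closure_eval(cls$markov, env)
  expect_lt(max(abs(rowSums(out[, 1:4]))), 1e-12)
  # Z^2-only closure at coefficient c reproduces the quadratic-mortality
  # missing-physics pattern: (0, 0, c Z^2, -c Z^2) and -(C_Z - C_D) c Z^2
  closure_set_w(cls$markov, c(0, 0, 0, 0,  0, 0, 0, 0,  0, -0.02998, 0, 0))
  out2 <- closure_eval(cls$markov, env)
  z2 <- env$u[, 3]^2
  expect_equal(out2[, 3], -0.02998 * z2, tolerance = 1e-12)
  expect_equal(out2[, 4], +0.02998 * z2, tolerance = 1e-12)
  expect_equal(out2[, 5], (params$C_Z - params$C_D) * 0.02998 * z2,
               tolerance = 1e-12)
  expect_equal(out2[, 5], -0.05621 * z2, tolerance = 1e-4)
  expect_true(all(out2[, c(1, 2, 6)] == 0))
})

test_that("the delay kernel of the augmented plankton model ignores DIC/TA", {
  set.seed(4)
  cls <- oa_closure_builder("2b", oa_params())
  n <- 10
  U <- matrix(abs(rnorm(n * 5)), n, 5L)
  env <- list(u = U, d = NULL, params = list(),
              exo = list(I = rep(50, n)))
  o1 <- closure_eval(cls$nonmark_cl, env)
  U2 <- U; U2[, 4] <- U2[, 4] + 100; U2[, 5] <- U2[, 5] * 2
  env2 <- env; env2$u <- U2
  expect_identical(o1, closure_eval(cls$nonmark_cl, env2))
  # biomass channels of the kernel output sum to zero by construction
  expect_lt(max(abs(rowSums(o1[, 1:3]))), 1e-12)
})

test_that("pruning freezes small weights only under an active l1 penalty", {
  cl <- closure_linear(lib_kdv(), n_raw = 1L)
  closure_set_w(cl, c(0.5, -0.001, 0.2, 0.04))
  res <- prune_and_penalty(cl, l1 = 1, l2 = 1, threshold = 0.01)
  expect_equal(as.numeric(cl$W), c(0.5, 0, 0.2, 0.04))
  expect_true(cl$frozen[2, 1])
  # frozen weights stay zero through weight updates
  closure_set_w(cl, c(1, 1, 1, 1))
  expect_equal(as.numeric(cl$W), c(1, 0, 1, 1))
  # without l1 there is no pruning regardless of the threshold
  cl2 <- closure_linear(lib_kdv(), n_raw = 1L)
  closure_set_w(cl2, c(0.5, -0.001, 0, 0))
  prune_and_penalty(cl2, l1 = 0, l2 = 1, threshold = 0.01)
  expect_false(any(cl2$frozen))
  # penalty arithmetic
  cl3 <- closure_linear(lib_kdv(), n_raw = 1L)
  closure_set_w(cl3, c(3, -4, 0, 0))
  expect_equal(prune_and_penalty(cl3, l1 = 1, l2 = 1, threshold = 0)$penalty,
               7 + 25)
})
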