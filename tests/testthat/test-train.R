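test_that("zero training epochs leave the closure untouched", {
  fx <- kdv_test_system(n_x = 64L, weights = c(0.1, -0.2, 0.3, 0))
  dat <- kdv_test_dataset(fx$grid, seq(0.01, 0.2, by = 0.01))
  cfg <- training_config(epochs = 0L, seed = 1L, batch_time = 0.01)
  res <- train(list(list(sys = fx$sys, data = dat, spec = loss_spec("mae"))),
               cfg)
  expect_equal(closure_get_w(fx$cl), c(0.1, -0.2, 0.3, 0))
  expect_null(res$history)
})

test_that("a planted library coefficient is recovered and decoys pruned", {
  res <- exp_planted_recovery(c_star = 0.7, term = 1L, n_x = 128L,
                              seed = 51L, epochs = 25L)
  rec <- res$recovered
  expect_lt(abs(rec["u_xx"] - 0.7) / 0.7, 0.05)
  expect_identical(unname(rec[c("u_xxx", "u.u_x", "u2.u_x")]), rep(0, 3))
})

test_that("training loss decreases over the first epochs of the recovery harness", {
  res <- exp_planted_recovery(c_star = 0.7, term = 1L, n_x = 96L,
                              seed = 52L, epochs = 10L,
                              steps_per_epoch = 6L)
  h <- res$history
  expect_lt(mean(tail(h$loss, 3)), mean(head(h$loss, 2)))
})

test_that("training history is reproducible under a fixed seed", {
  run_once <- function() {
    fx <- kdv_test_system(n_x = 64L)
    dat <- kdv_test_dataset(fx$grid, seq(0.01, 0.3, by = 0.01))
    cfg <- training_config(epochs = 3L, lr = 0.05, batch_time = 0.01,
                           batch_size = 1L, steps_per_epoch = 4L,
                           seed = 99L)
    train(list(list(sys = fx$sys, data = dat, spec = loss_spec("mae"))),
          cfg)$history
  }
  h1 <- run_once()
  h2 <- run_once()
  expect_identical(h1, h2)
})
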