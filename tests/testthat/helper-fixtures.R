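# Shared builders for small test systems. Everything is generated in code;
# sizes are kept small so the whole suite stays fast.

kdv_test_dataset <- function(grid, times, p = soliton_params()) {
  arr <- array(vapply(times, function(t) kdv_two_soliton(grid$x, t, p),
                      numeric(grid$n)), c(grid$n, 1L, length(times)))
  closure_dataset(times, arr, grid)
}

kdv_test_system <- function(n_x = 200L, weights = NULL, rtol = 1e-6,
                            atol = 1e-8, adj_dt = 2.5e-4) {
  p <- soliton_params()
  g <- grid1d(-p$L, p$L, n_x)
  cl <- closure_linear(lib_kdv(), n_raw = 1L)
  if (!is.null(weights)) closure_set_w(cl, weights)
  sys <- npdde_system(g, "u", wave_core(g, "kdv_lowfi"), markov = cl,
                      solver = list(method = "lsoda", bands = 6L,
                                    rtol = rtol, atol = atol,
                                    adj_dt = adj_dt, maxsteps = 2000,
                                    blowup_cap = 30))
  list(sys = sys, grid = g, cl = cl, p = p)
}

# small delayed plankton system for adjoint tests
oa_test_delay_system <- function(seed = 5L, hidden = c(6L, 6L),
                                 init_scale = 0.3, t_data = 10,
                                 dt_data = 0.5) {
  set.seed(seed)
  params <- oa_params(); physics <- oa_physics()
  g <- grid1d(0, physics$D_z, physics$N_z)
  truth <- oa_truth_data(list(t_data = t_data, dt_data = dt_data,
                              spinup_days = 30), params, physics)
  agg <- oa_aggregate_dataset(truth$data)
  cls <- oa_closure_builder("2b", params, tau = 2.5, hidden = hidden,
                            init_scale = init_scale)
  sys <- oa_system(g, params, physics, "npz_oa", "linear",
                   markov = cls$markov,
                   nonmark = list(cl = cls$nonmark_cl, tau = 2.5,
                                  history = function(t) {
                                    dataset_state(agg, max(t, agg$times[1]))
                                  }),
                   solver = list(rtol = 1e-9, atol = 1e-11, adj_dt = 0.005))
  list(sys = sys, agg = agg, grid = g, params = params, physics = physics,
       truth = truth, cls = cls)
}

expect_rel_equal <- function(x, y, tol) {
  expect_lt(abs(x - y) / max(abs(y), 1e-12), tol)
}
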