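# neuralclosure

Interpretable neural closure models for one-dimensional PDEs, trained with
continuous adjoints.

## What problem this solves

Reduced models — a wave equation missing its dispersive term, a coarse-grid
shock solver, a plankton model with an aggregated-away detritus pool — are
cheap but systematically wrong. This package augments such a low-fidelity
model

```
u_t = L(u, u_x, ...) + F_phi(u, u_x, ..., dx, nu)
      + ∫_{t-tau}^{t} D_theta(u(s), ..., s) ds
```

with two trainable closure terms: an instantaneous (Markovian) term
`F_phi`, usually a sparse linear combination over a library of candidate
terms so that the result is readable as equations, and a memory
(non-Markovian) term, a distributed-delay integral of a small neural
kernel `D_theta` that stands in for unresolved state variables. Both are
node-local and inserted at the PDE level before discretization, so the
learned weights transfer across grid resolutions, boundary conditions and
physical parameters. Gradients come from solving continuous adjoint PDEs
backward in time — the cost is independent of the number of weights — with
the data misfit entering as jumps in the adjoint at the snapshot times and
the delay term handled through a coupled memory state. Every gradient path
is verified against a finite-difference oracle in the test suite.

Intended users: researchers in closure/subgrid modelling and
ocean-biogeochemistry model calibration who want interpretable learned
corrections with a plain-R, deSolve-based stack.

Three study systems ship with the package:

1. **KdV–Burgers term discovery** — recover `-5 u u_x - u_xxx` (with two
   decoy library terms pruned to zero) from two-soliton data on top of an
   advection-only model.
2. **Burgers truncation-error discovery and generalization** — learn the
   leading truncation error of an under-resolved shock solver; the full
   library+kernel closure is evaluated over a 35-cell `(Nx, Re)` sweep
   against truncation-term and Smagorinsky baselines and under changed
   boundary conditions.
3. **Plankton–carbonate column (NPZD-OA)** — discriminate the zooplankton
   mortality law (linear vs quadratic) with a conservation-constrained
   mortality library, and augment an aggregated NPZ model with a memory
   closure so its year-long fields track the full model.

## Worked example

Recover the missing physics of the KdV–Burgers equation from two-soliton
snapshots (reduced size so it runs in about a minute):

```r
library(neuralclosure)

cfg <- kdv_discovery_config(seeds = 11L, epochs = 45L)
res <- exp_kdv_discovery(cfg)
round(res$mean_coef, 4)
#>   u_xx  u_xxx  u.u_x u2.u_x
#> 0.0000 -1.0024 -5.0122 0.0000
c(true_model = res$rmse_true, learned = res$rmse_learned_mean)
#> true_model    learned
#> 0.02409      0.00577
```

Reading: starting from `u_t = -u u_x`, training found the closure
`-5.01 u u_x - 1.00 u_xxx` and pruned the redundant `u_xx` and
`u^2 u_x` terms to exactly zero, i.e. it rediscovered the true equation
`u_t = -6 u u_x - u_xxx`. The closed model tracks the analytic two-soliton
solution about four times more accurately (snapshot-averaged RMSE 0.006)
than solving the true equation with the same numerics (0.024), because the
learned coefficients also compensate discretization error.

The plankton experiments run the same way:

```r
res2a <- exp_oa_discrimination(oa_discrimination_config(
  t_data = 20, dt_data = 0.25, seeds = c(31L, 32L)))
round(res2a$z2_contrib, 4)
#>       N       P       Z       D     DIC      TA
#>  0.0000  0.0000 -0.0283  0.0283 -0.0530  0.0000
```

— the closure attributes the model–data mismatch to a quadratic
zooplankton mortality `≈ -0.03 Z²` moving biomass from Z to detritus, with
the implied DIC contribution, and nothing on N, P or TA (the true values
are ±0.02998 and −0.05621).

YAML-driven runs and a thin command-line driver are available too:

```r
run_experiment(system.file("extdata/configs/kdv_discovery.yaml",
                           package = "neuralclosure"), out_dir = "runs/kdv")
```

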