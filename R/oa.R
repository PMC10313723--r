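# 1-D physical-biological-carbonate column models.
#
# High-fidelity: NPZD (nutrients, phytoplankton, zooplankton, detritus)
# with quadratic zooplankton mortality, coupled one-way to dissolved
# inorganic carbon (DIC) and total alkalinity (TA) through fixed C:N
# ratios, plus vertical eddy diffusion with a seasonally varying mixed
# layer. Low-fidelity variants: the same NPZD column with only linear
# mortality (mortality-law discrimination), and an aggregated NPZ column
# without the detritus pool (model-complexity augmentation).
#
# Depth z increases downward from 0 at the surface; time unit is days;
# biological state in mmol N m^-3, DIC in mmol C m^-3, TA in mmol C kg^-1.

#' Biological and carbonate parameters
#'
#' Rates are per day; half-saturations in mmol N m^-3. The quadratic
#' mortality coefficient is \code{m_Z/2 = 0.02998} and the C:N ratios
#' satisfy \code{C_Z - C_D = -1.875}, so the true quadratic-mortality
#' contributions to the (Z, D, DIC) equations are \code{-0.02998 Z^2},
#' \code{+0.02998 Z^2} and \code{-0.05621 Z^2}. Remaining defaults are
#' standard bloom-capable NPZD values.
#'
#' @param ... overrides of the default list.
#' @return named parameter list.
#' @export
oa_params <- function(...) {
  p <- list(
    mu_max = 2.0,        # phyto max growth, 1/d
    K_N = 1.0,           # N half-saturation
    alpha = -0.025,      # light-growth slope (enters as 1 - exp(alpha I / mu))
    beta = 0.01,         # light-inhibition coefficient
    k_W = 0.1,           # light attenuation, 1/m
    g_max = 1.0,         # zooplankton max grazing, 1/d
    K_P = 1.0,           # grazing half-saturation
    gamma = 0.7,         # assimilation fraction
    lambda_resp = 0.1,   # active respiration as fraction of grazing
    m_P = 0.05,          # phyto mortality, 1/d
    m_Z = 0.05996,       # zoo mortality coefficient (m_Z/2 = 0.02998)
    eps_remin = 0.1,     # detritus remineralization, 1/d
    C_P = 6.625, C_Z = 5.625, C_D = 7.5,   # C:N ratios
    gamma_c = 0.05,      # hard-flux (CaCO3) fraction of uptake
    rho_w = 1025)        # seawater density, kg m^-3
  utils::modifyList(p, list(...))
}

#' Column physics: depth grid, mixing, forcing, salinity
#'
#' The eddy diffusivity profile interpolates between the surface value and
#' the bottom value across the mixed-layer base with an arctan profile of
#' sharpness \code{gamma_t}. Surface irradiance and mixed-layer depth are
#' annual sinusoids (winter: deep mixing, low light).
#'
#' @param ... overrides.
#' @return physics list with \code{M(t)}, \code{I0(t)} functions.
#' @export
oa_physics <- function(...) {
  p <- list(
    D_z = 100, N_z = 20L,
    K_z0 = 50,           # surface diffusivity, m^2/d
    K_zb = 1,            # bottom diffusivity, m^2/d
    gamma_t = 0.3,       # thermocline sharpness, 1/m
    sal = list(A = 31.4, K = 32.8, C = 1.0, Q = 0.5, B = 0.25, nu = 2.0),
    I0_mean = 200, I0_amp = 100,   # W m^-2
    M_mean = 50, M_amp = 40,       # m
    phase_day0 = 80,               # simulation starts in early spring
    year = 365)
  p <- utils::modifyList(p, list(...))
  # t = 0 is day `phase_day0` of the calendar year: training windows of a
  # few weeks then cover the productive season whose dynamics excite the
  # mortality and detritus closures
  p$I0 <- function(t) {
    p$I0_mean - p$I0_amp * cos(2 * pi * (t + p$phase_day0) / p$year)
  }
  p$M <- function(t) {
    p$M_mean + p$M_amp * cos(2 * pi * (t + p$phase_day0) / p$year)
  }
  p$T_bio <- function(z) 3 + 7 / (1 + exp(-(z - 50) / 10))
  p
}

#' Forcing and static profiles at depth
#'
#' @param z depths (m, positive down).
#' @param t time (days).
#' @param physics from \code{\link{oa_physics}}.
#' @param params from \code{\link{oa_params}} (light attenuation).
#' @return list with irradiance \code{I}, eddy diffusivity \code{K_z},
#'   salinity \code{S} (PSU) and salinity-derived total alkalinity
#'   \code{TA_init} (mmol C kg^-1, piecewise-linear in S with breakpoint
#'   32.34 PSU).
#' @export
forcing_and_profiles <- function(z, t, physics = oa_physics(),
                                 params = oa_params()) {
  I <- physics$I0(t) * exp(-params$k_W * z)
  M <- physics$M(t)
  g <- physics$gamma_t
  Kz <- physics$K_zb + (physics$K_z0 - physics$K_zb) *
    (atan(-g * (M - z)) - atan(-g * (M - physics$D_z))) /
    (atan(-g * M) - atan(-g * (M - physics$D_z)))
  s <- physics$sal
  S <- s$A + (s$K - s$A) / (s$C + s$Q * exp(-s$B * z))^(1 / s$nu)
  TA <- ifelse(S < 32.34, (198.10 + 61.75 * S) / 1000,
               (744.41 + 44.86 * S) / 1000)
  list(I = I, K_z = Kz, S = S, TA_init = TA)
}

oa_state_names <- function(model_kind) {
  if (model_kind == "npzd_oa") c("N", "P", "Z", "D", "DIC", "TA")
  else c("N", "P", "Z", "DIC", "TA")
}

#' Reaction tendencies of the plankton-carbonate system
#'
#' @param state matrix (nodes x states) ordered as
#'   \code{\link{oa_state_names}}.
#' @param I irradiance at the nodes (W m^-2).
#' @param params from \code{\link{oa_params}}.
#' @param model_kind "npzd_oa" (4-component biology + carbonate) or
#'   "npz_oa" (aggregated, no detritus).
#' @param mortality_kind "linear" (\code{m_Z/2 Z}) or "quadratic"
#'   (\code{m_Z/2 (Z + Z^2)}); the NPZ model always uses linear.
#' @return tendency matrix (nodes x states).
#' @export
biogeochem_rhs <- function(state, I, params, model_kind = "npzd_oa",
                           mortality_kind = "quadratic") {
  p <- params
  N <- state[, 1L]; P <- state[, 2L]; Z <- state[, 3L]
  f_N <- N / (N + p$K_N)
  f_I <- (1 - exp(p$alpha * I / p$mu_max)) * exp(-p$beta * I / p$mu_max)
  U_P <- p$mu_max * f_N * f_I * P
  G_Z <- p$g_max * Z * P^2 / (P^2 + p$K_P^2)
  out <- state * 0
  if (model_kind == "npzd_oa") {
    D <- state[, 4L]
    M_Z <- if (mortality_kind == "quadratic") p$m_Z / 2 * (Z + Z^2)
           else p$m_Z / 2 * Z
    dN <- -U_P + p$lambda_resp * G_Z + p$eps_remin * D
    dP <- U_P - G_Z - p$m_P * P
    dZ <- p$gamma * G_Z - M_Z
    dD <- (1 - p$gamma - p$lambda_resp) * G_Z + p$m_P * P + M_Z -
      p$eps_remin * D
    dDIC <- -p$C_P * dP - p$C_Z * dZ - p$C_D * dD - p$gamma_c * p$C_P * U_P
    dTA <- -dN / p$rho_w - 2 * p$gamma_c * p$C_P * U_P / p$rho_w
    out[, 1L] <- dN; out[, 2L] <- dP; out[, 3L] <- dZ; out[, 4L] <- dD
    out[, 5L] <- dDIC; out[, 6L] <- dTA
  } else {
    dN <- -U_P + (1 - p$gamma) * G_Z + p$m_P * P + p$m_Z / 2 * Z
    dP <- U_P - G_Z - p$m_P * P
    dZ <- p$gamma * G_Z - p$m_Z / 2 * Z
    dDIC <- -p$C_P * dP - p$C_Z * dZ - p$gamma_c * p$C_P * U_P
    dTA <- -dN / p$rho_w - 2 * p$gamma_c * p$C_P * U_P / p$rho_w
    out[, 1L] <- dN; out[, 2L] <- dP; out[, 3L] <- dZ
    out[, 4L] <- dDIC; out[, 5L] <- dTA
  }
  out
}

# half-level diffusivities for the conservative no-flux diffusion operator
oa_k_half <- function(grid, physics, t) {
  zh <- (grid$x[-1] + grid$x[-grid$n]) / 2
  forcing_and_profiles(zh, t, physics)$K_z
}

#' Column model core (reaction + vertical eddy diffusion)
#'
#' Conservative second-order flux-form diffusion with zero-flux boundaries
#' at surface and bottom (the column conserves depth-integrated biomass up
#' to reaction terms). The transposed Jacobian combines the (symmetric)
#' diffusion operator with node-local numerically-differentiated reaction
#' blocks.
#'
#' @param grid depth grid from \code{\link{grid1d}} (0 at surface).
#' @param params from \code{\link{oa_params}}.
#' @param physics from \code{\link{oa_physics}}.
#' @param model_kind,mortality_kind see \code{\link{biogeochem_rhs}}.
#' @param diffusion set FALSE for the reaction-only (spin-up) system.
#' @param I0_const optional constant surface irradiance (spin-up).
#' @return core list for \code{\link{npdde_system}}.
#' @export
oa_core <- function(grid, params = oa_params(), physics = oa_physics(),
                    model_kind = "npzd_oa", mortality_kind = "quadratic",
                    diffusion = TRUE, I0_const = NULL) {
  ns <- length(oa_state_names(model_kind))
  n <- grid$n
  dz <- grid$dx
  irr <- function(t) {
    I0 <- if (is.null(I0_const)) physics$I0(t) else I0_const
    I0 * exp(-params$k_W * grid$x)
  }
  react <- function(t, U) {
    biogeochem_rhs(U, irr(t), params, model_kind, mortality_kind)
  }
  diffuse <- function(t, U) {
    kh <- oa_k_half(grid, physics, t)
    flux <- kh * (U[-1L, , drop = FALSE] - U[-n, , drop = FALSE]) / dz
    (rbind(flux, 0) - rbind(0, flux)) / dz
  }
  ev <- function(t, U, sys) {
    dU <- react(t, U)
    if (diffusion) dU <- dU + diffuse(t, U)
    dU
  }
  # node-local reaction Jacobian by finite differences (6 extra vectorized
  # reaction evaluations per assembly)
  react_jac <- function(ctx) {
    if (!is.null(ctx$cache$RJ)) return(ctx$cache$RJ)
    U <- ctx$U
    base <- react(ctx$t, U)
    J <- array(0, c(n, ns, ns))     # node, s_out, s_in
    for (s in seq_len(ns)) {
      h <- 1e-6 * max(1, max(abs(U[, s])))
      U2 <- U; U2[, s] <- U2[, s] + h
      J[, , s] <- (react(ctx$t, U2) - base) / h
    }
    ctx$cache$RJ <- J
    J
  }
  jt_parts <- function(sys) {
    parts <- list()
    for (si in seq_len(ns)) {
      for (so in seq_len(ns)) {
        local({
          si_ <- si; so_ <- so
          parts[[length(parts) + 1L]] <<- list(
            D = NULL, s_in = si_, s_out = so_,
            coef = function(ctx) react_jac(ctx)[, so_, si_])
        })
      }
    }
    if (diffusion) {
      Dsup <- Matrix::sparseMatrix(i = seq_len(n - 1L), j = 2:n, x = 1,
                                   dims = c(n, n))
      Dsub <- Matrix::sparseMatrix(i = 2:n, j = seq_len(n - 1L), x = 1,
                                   dims = c(n, n))
      khf <- function(ctx) {
        if (is.null(ctx$cache$kh)) ctx$cache$kh <- oa_k_half(grid, physics, ctx$t)
        ctx$cache$kh
      }
      for (s in seq_len(ns)) {
        local({
          s_ <- s
          parts[[length(parts) + 1L]] <<- list(
            D = Dsup, s_in = s_, s_out = s_,
            coef = function(ctx) c(khf(ctx), 0) / dz^2)
          parts[[length(parts) + 1L]] <<- list(
            D = Dsub, s_in = s_, s_out = s_,
            coef = function(ctx) c(0, khf(ctx)) / dz^2)
          parts[[length(parts) + 1L]] <<- list(
            D = NULL, s_in = s_, s_out = s_,
            coef = function(ctx) -(c(0, khf(ctx)) + c(khf(ctx), 0)) / dz^2)
        })
      }
    }
    parts
  }
  list(eval = ev, jt_parts = jt_parts, pinned = NULL, bcs = NULL,
       kind = model_kind, react = react, irr = irr)
}

#' Spin-up initialization of the column
#'
#' Starts from nutrients carrying the full biomass profile (with a small
#' seed fraction moved into P and Z so growth and grazing can act),
#' integrates the reaction system node-wise (no diffusion) under constant
#' surface irradiance, and returns the resulting near-equilibrium state
#' as initial conditions. DIC is initialized as C_P times the equilibrium
#' nutrient concentration and TA from the salinity profile.
#'
#' @param grid depth grid.
#' @param params,physics model setup.
#' @param model_kind,mortality_kind see \code{\link{biogeochem_rhs}}.
#' @param days spin-up length (days).
#' @param seed_frac fraction of total biomass seeded into P and Z.
#' @param tol relative-tendency threshold for the equilibrium warning.
#' @return state matrix (nodes x states).
#' @export
spinup_init <- function(grid, params = oa_params(), physics = oa_physics(),
                        model_kind = "npzd_oa",
                        mortality_kind = "quadratic", days = 30,
                        seed_frac = 1e-3, tol = 1e-6) {
  ns <- length(oa_state_names(model_kind))
  n <- grid$n
  Tb <- physics$T_bio(grid$x)
  U0 <- matrix(0, n, ns)
  U0[, 2L] <- seed_frac * Tb
  U0[, 3L] <- seed_frac * Tb
  U0[, 1L] <- Tb - U0[, 2L] - U0[, 3L]
  core <- oa_core(grid, params, physics, model_kind, mortality_kind,
                  diffusion = FALSE, I0_const = physics$I0(0))
  sys <- npdde_system(grid, oa_state_names(model_kind), core,
                      solver = list(method = "lsoda", rtol = 1e-8,
                                    atol = 1e-10, hmax = 1))
  traj <- solve_forward(sys, U0, c(0, days / 2, days))
  Ueq <- traj_state(traj, days)
  resid <- core$eval(days, Ueq, sys)
  bio <- seq_len(if (model_kind == "npzd_oa") 4L else 3L)
  rel <- max(abs(resid[, bio])) / max(abs(Ueq[, bio]))
  if (rel > tol) {
    warning(sprintf("spin-up not fully converged: relative tendency %.3g", rel))
  }
  fp <- forcing_and_profiles(grid$x, 0, physics, params)
  i_dic <- if (model_kind == "npzd_oa") 5L else 4L
  Ueq[, i_dic] <- params$C_P * Ueq[, 1L]
  Ueq[, i_dic + 1L] <- fp$TA_init
  Ueq
}

# mortality-law candidate library (functions of Z at a given state index)
lib_mortality <- function(iZ = 3L) {
  zf <- function(e) e$u[, iZ]
  function_library(
    library_term("Z", function(e) zf(e),
                 list(list(state = iZ, order = 0L,
                           fn = function(e) rep(1, nrow(e$u))))),
    library_term("Z2", function(e) zf(e)^2,
                 list(list(state = iZ, order = 0L,
                           fn = function(e) 2 * zf(e)))),
    library_term("Z2_over_1pZ", function(e) zf(e)^2 / (1 + zf(e)),
                 list(list(state = iZ, order = 0L,
                           fn = function(e) (zf(e)^2 + 2 * zf(e)) / (1 + zf(e))^2))),
    library_term("expZ", function(e) exp(zf(e)),
                 list(list(state = iZ, order = 0L,
                           fn = function(e) exp(zf(e))))))
}

#' Constrained closures for the plankton-carbonate experiments
#'
#' Mortality-discrimination ("2a"): a linear closure over the candidate
#' mortality library with three free output channels per term (N, P, Z);
#' the D channel balances biomass exactly and the DIC/TA channels follow
#' the fixed C:N coupling, all by construction of the channel map.
#'
#' Complexity augmentation ("2b"): the same library with a single free
#' channel (Z), the P contribution pinned to zero and N balancing Z, plus
#' a delay-kernel network on inputs (N, P, Z, I) whose three raw outputs
#' are projected onto the zero-sum (biomass-conserving) subspace and
#' coupled to DIC/TA; DIC and TA are not inputs, preserving the one-way
#' biology-to-carbonate coupling.
#'
#' @param experiment "2a" or "2b".
#' @param params from \code{\link{oa_params}}.
#' @param tau delay for the 2b memory closure (days).
#' @param hidden hidden-layer widths of the delay kernel.
#' @param init_scale initialization scale of the delay kernel.
#' @return list with \code{markov} and (2b) \code{nonmark_cl}, \code{tau}.
#' @export
oa_closure_builder <- function(experiment = c("2a", "2b"),
                               params = oa_params(), tau = 2.5,
                               hidden = c(24L, 24L), init_scale = 0.1,
                               out_clamp = 0.5) {
  experiment <- match.arg(experiment)
  p <- params
  if (experiment == "2a") {
    # raw channels (rN, rP, rZ); D = -(rN+rP+rZ); DIC/TA per Eqs. of the
    # known system; TA couples only through the N tendency
    A <- rbind(
      N   = c(1, 0, 0),
      P   = c(0, 1, 0),
      Z   = c(0, 0, 1),
      D   = c(-1, -1, -1),
      DIC = c(p$C_D, p$C_D - p$C_P, p$C_D - p$C_Z),
      TA  = c(-1 / p$rho_w, 0, 0))
    markov <- closure_linear(lib_mortality(3L), n_raw = 3L, channel_map = A)
    return(list(markov = markov))
  }
  # 2b Markovian: single free channel; the P contribution is pinned to
  # zero, N balances Z (aggregated biomass conservation) and the carbonate
  # channels follow the fixed C:N coupling of the aggregated model
  A1 <- rbind(N = -1, P = 0, Z = 1, DIC = -p$C_Z, TA = 1 / p$rho_w)
  markov <- closure_linear(lib_mortality(3L), n_raw = 1L, channel_map = A1)
  # 2b non-Markovian: raw (r1,r2,r3) -> zero-sum (N,P,Z) by projection
  Pz <- diag(3) - matrix(1 / 3, 3, 3)
  A2 <- rbind(Pz,
              DIC = -p$C_P * Pz[2, ] - p$C_Z * Pz[3, ],
              TA  = -Pz[1, ] / p$rho_w)
  rownames(A2)[1:3] <- c("N", "P", "Z")
  inputs <- list(
    list(kind = "state", state = 1L, name = "N", center = 5, scale = 5),
    list(kind = "state", state = 2L, name = "P", center = 1, scale = 1),
    list(kind = "state", state = 3L, name = "Z", center = 1, scale = 1),
    list(kind = "exo", name = "I", center = 100, scale = 100))
  nonmark <- closure_deep(inputs, hidden = hidden, n_raw = 3L,
                          channel_map = A2, init_scale = init_scale,
                          out_clamp = out_clamp)
  list(markov = markov, nonmark_cl = nonmark, tau = tau)
}

#' Assemble an ocean-acidification column system
#'
#' @param grid depth grid.
#' @param params,physics model setup.
#' @param model_kind,mortality_kind see \code{\link{biogeochem_rhs}}.
#' @param markov,nonmark optional closures (see
#'   \code{\link{oa_closure_builder}}); \code{nonmark} is
#'   \code{list(cl, tau, history)}.
#' @param solver solver overrides.
#' @return an \code{\link{npdde_system}}.
#' @export
oa_system <- function(grid, params = oa_params(), physics = oa_physics(),
                      model_kind = "npzd_oa", mortality_kind = "quadratic",
                      markov = NULL, nonmark = NULL, solver = list()) {
  core <- oa_core(grid, params, physics, model_kind, mortality_kind)
  sv <- utils::modifyList(
    list(method = "ode45", rtol = 1e-6, atol = 1e-8, adj_dt = 0.02,
         blowup_cap = 1e5, hmax = 0.5), solver)
  npdde_system(grid, oa_state_names(model_kind), core,
               markov = markov, nonmarkov = nonmark,
               exo_fn = function(t) list(I = core$irr(t)),
               solver = sv)
}

#' Aggregate an NPZD-OA dataset to the NPZ-OA state space
#'
#' Detritus is folded into the nutrient pool (N+D); the other channels are
#' carried over. Used as truth for training/evaluating the aggregated
#' low-fidelity model.
#'
#' @param data a 6-channel \code{\link{closure_dataset}}.
#' @return a 5-channel \code{\link{closure_dataset}}.
#' @export
oa_aggregate_dataset <- function(data) {
  arr <- array(0, c(data$n, 5L, length(data$times)))
  arr[, 1L, ] <- data$U[, 1L, ] + data$U[, 4L, ]
  arr[, 2L, ] <- data$U[, 2L, ]
  arr[, 3L, ] <- data$U[, 3L, ]
  arr[, 4L, ] <- data$U[, 5L, ]
  arr[, 5L, ] <- data$U[, 6L, ]
  closure_dataset(data$times, arr, data$grid)
}
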