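# Experiment registry, configuration files, and run manifests.

experiment_registry <- function() {
  list(
    kdv_discovery = function(cfg) {
      do.call(kdv_discovery_config, cfg) |> exp_kdv_discovery()
    },
    burgers_markovian = function(cfg) {
      do.call(burgers_markov_config, cfg) |> exp_burgers_discovery()
    },
    burgers_full = function(cfg) {
      cfg$with_nonmarkov <- TRUE
      do.call(burgers_markov_config, cfg) |> exp_burgers_discovery()
    },
    burgers_sweep = function(cfg) {
      fit <- {
        cfg2 <- cfg; cfg2$with_nonmarkov <- TRUE
        do.call(burgers_markov_config, cfg2) |> exp_burgers_discovery()
      }
      lat <- sweep_lattice()
      fac <- sweep_system_factory("learned", fit$markov, fit$nonmark_cl,
                                  fit$cfg$tau)
      list(fit = fit, sweep = generalization_sweep(fac, lat$Nx, lat$Re))
    },
    burgers_dirichlet = function(cfg) {
      cfg2 <- cfg; cfg2$with_nonmarkov <- TRUE
      fit <- do.call(burgers_markov_config, cfg2) |> exp_burgers_discovery()
      exp_burgers_dirichlet(fit$markov, fit$nonmark_cl, fit$cfg$tau)
    },
    oa_discrimination = function(cfg) {
      do.call(oa_discrimination_config, cfg) |> exp_oa_discrimination()
    },
    oa_complexity = function(cfg) {
      fit <- do.call(oa_complexity_config, cfg) |> exp_oa_complexity()
      fit$forecast <- oa_complexity_forecast(fit)
      fit
    },
    gradient_check = function(cfg) {
      do.call(exp_gradient_check, cfg)
    },
    planted_recovery = function(cfg) {
      do.call(exp_planted_recovery, cfg)
    })
}

#' Adjoint-gradient verification experiment
#'
#' Builds a small KdV library-closure system at random weights and compares
#' adjoint gradients against central finite differences of the loss.
#'
#' @param n_x grid size.
#' @param seed RNG seed.
#' @param n_sample weights tested.
#' @return list with \code{max_rel_err} and the comparison table.
#' @export
exp_gradient_check <- function(n_x = 200L, seed = 7L, n_sample = 4L) {
  set.seed(seed)
  p <- soliton_params()
  g <- grid1d(-p$L, p$L, n_x)
  tt <- seq(0.01, 1.0, by = 0.01)
  dat <- kdv_truth_dataset(g, tt, p)
  cl <- closure_linear(lib_kdv(), n_raw = 1L)
  closure_set_w(cl, c(-0.05, -0.5, -2, -0.3))
  sys <- npdde_system(g, "u", wave_core(g, "kdv_lowfi"), markov = cl,
                      solver = list(method = "lsoda", bands = 6L,
                                    rtol = 1e-9, atol = 1e-11,
                                    adj_dt = 1e-4))
  gradient_check(sys, dat, loss_spec("mae"), kdv_two_soliton(g$x, 0.30, p),
                 0.30, 0.33, n_sample = n_sample)
}

#' List available experiments
#' @return character vector of experiment ids.
#' @export
list_experiments <- function() names(experiment_registry())

#' Run an experiment from a configuration
#'
#' @param config either a list with an \code{experiment} field (plus
#'   overrides of that experiment's defaults) or the path of a YAML file
#'   with the same structure.
#' @param out_dir optional artifact directory: results (RDS), a resolved
#'   YAML manifest (config, seed, package version, R version) and a
#'   metrics summary are written there.
#' @return the experiment result (invisibly when writing artifacts).
#' @export
run_experiment <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (is.null(config$experiment)) stop("config$experiment is missing")
  reg <- experiment_registry()
  id <- config$experiment
  if (!id %in% names(reg)) {
    stop("unknown experiment id '", id, "'; see list_experiments()")
  }
  cfg <- config
  cfg$experiment <- NULL
  res <- reg[[id]](cfg)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    saveRDS(res, file.path(out_dir, "result.rds"))
    manifest <- list(
      experiment = id, config = cfg,
      package_version = as.character(utils::packageVersion("neuralclosure")),
      r_version = R.version.string,
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
    yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
    return(invisible(res))
  }
  res
}

#' Serialize learned linear-closure coefficients to columnar text
#' @param cl a \code{closure_linear}.
#' @param path output TSV path.
#' @return the written data frame, invisibly.
#' @export
write_coefficients <- function(cl, path) {
  df <- data.frame(term = rep(cl$lib$names, ncol(cl$W)),
                   channel = rep(seq_len(ncol(cl$W)), each = nrow(cl$W)),
                   weight = as.numeric(cl$W),
                   frozen = as.logical(cl$frozen))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(df)
}
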