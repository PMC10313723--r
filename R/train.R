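# Stochastic-gradient training of closure weights. Each step samples short
# sub-trajectories ("batch-time" windows) from the truth data, restarts the
# forward model from the interpolated truth at the window start, solves
# forward, solves the adjoint backward, and updates the shared closure
# weights with Adam. Pruning of small library weights is enabled after a
# burn-in so that zero-initialized coefficients are not frozen before they
# have moved.

#' Training configuration
#'
#' @param epochs number of passes over the training cases.
#' @param lr Adam step size.
#' @param lr_decay geometric per-epoch decay of the step size.
#' @param batch_time length of each training sub-interval (time units).
#' @param batch_size sub-intervals averaged per gradient step.
#' @param steps_per_epoch gradient steps per case per epoch (NULL = as many
#'   disjoint windows as the data allows).
#' @param l1,l2 regularization weights on the closure parameters.
#' @param prune_threshold magnitude below which library weights are frozen
#'   to zero (active only when \code{l1 > 0}).
#' @param prune_after fraction of epochs before pruning becomes active.
#' @param seed RNG seed; fully determines window sampling and
#'   initialization.
#' @param val_fn optional function(sys_list) returning a validation loss;
#'   evaluated each epoch, and the best-validation weights are restored at
#'   the end of training.
#' @param lr_deep_scale multiplier on the step size for deep-closure
#'   weights (the interpretable library coefficients typically need a
#'   larger step than the kernel network); 0 freezes the deep closures.
#' @param lr_markov_scale multiplier on the step size for library-closure
#'   weights; 0 freezes them (used for staged fits).
#' @param adam_beta1,adam_beta2,adam_eps Adam moment parameters.
#' @param adam_eps_rel relative damping: the effective epsilon is
#'   \code{adam_eps + adam_eps_rel * mean(sqrt(v_hat))}, so directions whose
#'   gradients are far below the typical gradient magnitude take
#'   proportionally small steps instead of full-size normalized steps (this
#'   keeps near-irrelevant library terms from wandering into unstable
#'   territory, e.g. anti-diffusive coefficients).
#' @return a \code{"training_config"}.
#' @export
training_config <- function(epochs = 40L, lr = 0.05, lr_decay = 0.95,
                            batch_time = 0.05, batch_size = 2L,
                            steps_per_epoch = NULL, l1 = 1e-4, l2 = 1e-4,
                            prune_threshold = 0.05, prune_after = 0.5,
                            seed = 1L, val_fn = NULL,
                            adam_beta1 = 0.9, adam_beta2 = 0.999,
                            adam_eps = 1e-8, adam_eps_rel = 0.02,
                            lr_deep_scale = 1, lr_markov_scale = 1) {
  structure(as.list(environment()), class = "training_config")
}

#' Train closure weights on one or more cases
#'
#' @param cases list of training cases, each
#'   \code{list(sys =, data =, spec =)}; all cases must reference the same
#'   closure environments (weights are shared).
#' @param config a \code{\link{training_config}}.
#' @return list with \code{history} (per-epoch data frame: loss, validation
#'   loss, named library coefficients), \code{best_epoch}, and
#'   \code{coefficients} (after restoring best-validation weights).
#' @export
train <- function(cases, config) {
  stopifnot(length(cases) >= 1L)
  set.seed(config$seed)
  cls <- sys_closures(cases[[1L]]$sys)
  if (!length(cls)) stop("system has no trainable closure")
  w <- closures_get_w(cls)
  lr_scale <- unlist(lapply(cls, function(cl) {
    rep(if (cl$kind == "deep") config$lr_deep_scale
        else config$lr_markov_scale, closure_n_w(cl))
  }), use.names = FALSE)
  m <- numeric(length(w)); v <- numeric(length(w))
  it <- 0L
  history <- list()
  best_val <- Inf; best_epoch <- 0L; best_w <- w
  if (!is.null(config$val_fn)) {
    v0 <- config$val_fn(lapply(cases, `[[`, "sys"))
    if (is.finite(v0)) best_val <- v0    # initial weights are a candidate
  }
  diverged <- FALSE
  n_failed <- 0L
  w_prev <- w

  coef_names <- if (!is.null(cls$markov) && cls$markov$kind == "linear")
    cls$markov$w_names else character(0)

  for (ep in seq_len(config$epochs)) {
    lr_ep <- config$lr * config$lr_decay^(ep - 1L)
    ep_losses <- c()
    for (ci in sample(seq_along(cases))) {
      cs <- cases[[ci]]
      tmax <- max(cs$data$times)
      starts <- cs$data$times[cs$data$times + config$batch_time <= tmax + 1e-12]
      if (!length(starts)) stop("batch_time exceeds the training horizon")
      n_steps <- max(1L, floor(length(starts) / config$batch_size))
      if (!is.null(config$steps_per_epoch)) {
        n_steps <- min(n_steps, config$steps_per_epoch)
      }
      pool <- sample(starts)
      for (st in seq_len(n_steps)) {
        take <- pool[seq_len(config$batch_size)]
        pool <- c(pool[-seq_len(config$batch_size)], take)
        run_batch <- function() {
          g <- numeric(length(w))
          n_ok <- 0L
          for (t_start in take) {
            t_end0 <- t_start + config$batch_time
            win <- cs$data$times[cs$data$times > t_start + 1e-12 &
                                   cs$data$times <= t_end0 + 1e-12]
            t_end <- max(win)
            U0 <- dataset_state(cs$data, t_start)
            sysw <- window_system(cs$sys, cs$data, t_start)
            traj <- tryCatch(
              suppressWarnings(solve_forward(sysw, U0, snap_times(c(t_start, win)))),
              error = function(e) NULL)
            if (is.null(traj) || !all(is.finite(traj$Y))) {
              n_failed <<- n_failed + 1L
              next
            }
            res <- adjoint_pass(sysw, traj, cs$data, cs$spec, t_start, t_end)
            g <- g + c(res$g_markov, res$g_nonmark)
            n_ok <- n_ok + 1L
            ep_losses <<- c(ep_losses,
                            loss_eval(traj, cs$data, cs$spec, t_start, t_end))
          }
          list(g = g, n_ok = n_ok)
        }
        # if every window in the batch blows up, the last update walked into
        # an unstable region of weight space: backtrack toward the last
        # stable iterate (keeping the stable part of the progress), reset
        # the momentum, and retry the same batch so that gradient flow
        # continues on every step
        b <- run_batch()
        halvings <- 0L
        while (b$n_ok == 0L && halvings < 8L) {
          w <- (w + w_prev) / 2
          closures_set_w(cls, w)
          w <- closures_get_w(cls)
          m[] <- 0
          halvings <- halvings + 1L
          b <- run_batch()
        }
        g <- b$g; n_ok <- b$n_ok
        if (n_ok == 0L) next
        w_prev <- w
        g <- g / n_ok
        if (!all(is.finite(g))) { diverged <- TRUE; break }
        g <- g + unlist(lapply(cls, penalty_grad, l1 = config$l1,
                               l2 = config$l2), use.names = FALSE)
        it <- it + 1L
        m <- config$adam_beta1 * m + (1 - config$adam_beta1) * g
        v <- config$adam_beta2 * v + (1 - config$adam_beta2) * g^2
        mh <- m / (1 - config$adam_beta1^it)
        vh <- v / (1 - config$adam_beta2^it)
        eps_t <- config$adam_eps + config$adam_eps_rel * mean(sqrt(vh))
        w <- w - (lr_ep * lr_scale) * mh / (sqrt(vh) + eps_t)
        closures_set_w(cls, w)
        w <- closures_get_w(cls)   # frozen entries forced back to zero
      }
      if (diverged) break
    }
    if (diverged) {
      warning("training aborted: non-finite loss or failed forward solve")
      break
    }
    if (ep >= config$prune_after * config$epochs) {
      for (cl in cls) {
        prune_and_penalty(cl, config$l1, config$l2, config$prune_threshold)
      }
      w <- closures_get_w(cls)
    }
    val <- NA_real_
    if (!is.null(config$val_fn)) {
      val <- config$val_fn(lapply(cases, `[[`, "sys"))
      if (is.finite(val) && val < best_val) {
        best_val <- val; best_epoch <- ep; best_w <- w
      }
    }
    row <- data.frame(epoch = ep, loss = mean(ep_losses), val = val)
    if (length(coef_names)) {
      cf <- as.numeric(cls$markov$W)
      names(cf) <- coef_names
      row <- cbind(row, as.data.frame(as.list(cf), check.names = FALSE))
    }
    history[[ep]] <- row
  }
  if (!is.null(config$val_fn) && is.finite(best_val)) {
    closures_set_w(cls, best_w)
  }
  out <- list(history = do.call(rbind, history),
              best_epoch = best_epoch, best_val = best_val,
              diverged = diverged, n_failed_windows = n_failed)
  if (!is.null(cls$markov) && cls$markov$kind == "linear") {
    out$coefficients <- closure_coefficients(cls$markov)
  }
  out
}

# a copy of the system whose delay history follows the truth data before the
# window start (training windows restart from data, so the memory of the
# delay term must also come from the data)
window_system <- function(sys, data, t_start) {
  if (is.null(sys$nonmarkov)) return(sys)
  t_min <- data$times[1]
  sys$nonmarkov$history <- function(t) {
    dataset_state(data, max(t, t_min))
  }
  sys
}
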