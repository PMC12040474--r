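#' Heuristic starting values for the multilevel fit
#'
#' Builds a base start from the data (per participant: yes-weighted mean
#' RSA for the midpoint, the RSA span of cells with yes-proportion above
#' one half for the criterion separation with the half RSA range as
#' fallback, a quarter of the RSA span for the flank noise, zero
#' log-ratio and coefficients, lapse 0.02) and jitters it with
#' seed-controlled Gaussian noise for the remaining starts, so a fixed
#' seed yields an identical start sequence.
#'
#' @param table aggregated binomial table (or internal model data).
#' @param seed integer seed driving the jitter.
#' @param n_starts number of starting vectors.
#' @param jitter overall jitter scale multiplier (start 1 is never
#'   jittered).
#' @return matrix with `n_starts` rows, one full parameter vector
#'   (optimizer scale) per row.
#' @export
initial_values <- function(table, seed = 1, n_starts = 1, jitter = 1) {
  md <- as_model_data(table)
  np <- md$n_participants
  rng <- range(md$cells$rsa)
  span <- max(diff(rng), 1)
  V <- matrix(0, np, .N_IND)
  degenerate <- FALSE
  for (i in seq_len(np)) {
    sel <- md$cells$p == i
    rsa <- md$cells$rsa[sel]; n <- md$cells$n[sel]; y <- md$cells$y[sel]
    if (sum(y) == 0 || sum(y) == sum(n)) {
      degenerate <- TRUE
      tau0 <- mean(rng); delta0 <- span / 2
    } else {
      tau0 <- sum(y * rsa) / sum(y)
      hi <- rsa[y / n > 0.5]
      delta0 <- if (length(hi) >= 2) max(diff(range(hi)), span / 20)
                else span / 2
    }
    sigma0 <- span / 4
    V[i, .I_TAU] <- tau0 / .MS_SCALE
    V[i, .I_DELTA] <- log(delta0 / .MS_SCALE)
    V[i, .I_SIGMA] <- log(sigma0 / .MS_SCALE)
    V[i, .I_LAPSE] <- lapse_to_logit(0.02)
  }
  if (degenerate) {
    warning("all-yes or all-no participant(s): wide default start used")
  }
  mu <- colMeans(V[, .GRP_COLS, drop = FALSE])
  sds <- apply(V[, .GRP_COLS, drop = FALSE], 2, stats::sd)
  sds[!is.finite(sds) | sds < 0.1] <- 0.1
  eta <- log(sds - .SD_FLOOR)
  base <- pack_par(V, mu, eta, mean(V[, .I_LAPSE]))

  # jitter scales: individual z-scores are unit scale; the lapse column
  # and group block get parameter-appropriate scales
  scales <- rep(0.5, .N_IND)
  scales[.I_LAPSE] <- 0.7
  grp_scales <- numeric(.N_IND)
  grp_scales[c(.I_TAU, .I_DELTA, .I_SIGMA)] <- 0.3
  grp_scales[.I_M] <- 0.2
  grp_scales[.I_BTAU] <- 0.15
  grp_scales[c(.I_BDELTA, .I_BSIGMA)] <- 0.15
  grp_scales[.I_BM] <- 0.1
  k <- length(.GRP_COLS)
  sc_all <- c(rep(scales, each = np), grp_scales[.GRP_COLS], rep(0.3, k),
              0.5) * jitter

  with_seed(seed, {
    out <- matrix(NA_real_, n_starts, length(base))
    out[1, ] <- base
    if (n_starts > 1) {
      for (s in 2:n_starts) {
        out[s, ] <- base + stats::rnorm(length(base)) * sc_all
      }
    }
    out
  })
}

#' Fit the multilevel observer model
#'
#' Maximizes the joint penalized log-likelihood (data likelihood plus
#' group-density terms for every individual parameter; see
#' [joint_log_likelihood()]) over all `33 * n + 65` parameters with
#' L-BFGS-B and analytic gradients, from `n_starts` seed-controlled
#' starting points. This is a joint-mode (penalized) maximum-likelihood
#' fit: individual and group parameters are maximized together, the
#' group densities acting as adaptive shrinkage penalties.
#'
#' @param table aggregated binomial table from [aggregate_trials()].
#' @param n_starts number of optimizer starts (default 20).
#' @param seed master seed for start jitter.
#' @param maxit L-BFGS-B iteration cap per start.
#' @param factr L-BFGS-B convergence tolerance (see [stats::optim()]).
#' @param warm_start optional full parameter vector used as start 1
#'   (remaining starts jitter it).
#' @param jitter jitter scale multiplier for starts beyond the first.
#' @return object of class `recal_fit`: `group` ([group_params()]),
#'   `participants` (list of [participant_params()]), `loglik`,
#'   `per_start` (tibble of start, loglik, converged), `par` (internal
#'   vector), `seed`, and the model data.
#' @export
fit_observer_model <- function(table, n_starts = 20, seed = 1,
                               maxit = 2000, factr = 1e7,
                               warm_start = NULL, jitter = 1) {
  md <- as_model_data(table)
  if (length(md$flank_fixed) > 0) {
    warning(sprintf(
      "%d participant(s) with < 2 distinct RSAs: flank parameters held at group means",
      length(md$flank_fixed)))
  }
  starts <- initial_values(md, seed = seed, n_starts = n_starts,
                           jitter = jitter)
  if (!is.null(warm_start)) {
    stopifnot(length(warm_start) == ncol(starts))
    delta <- starts - matrix(starts[1, ], n_starts, ncol(starts),
                             byrow = TRUE)
    starts <- matrix(warm_start, n_starts, ncol(starts), byrow = TRUE) + delta
  }
  lower <- par_lower(md$n_participants)
  run1 <- function(p0) {
    obj <- make_objective(md)
    r <- stats::optim(pmax(p0, lower), fn = obj$fn, gr = obj$gr,
                      method = "L-BFGS-B", lower = lower,
                      control = list(maxit = maxit, factr = factr))
    # line-search failures (code 52) can occur at the probability-floor
    # kink; restarting from the current point usually clears them
    tries <- 0L
    while (r$convergence == 52L && tries < 3L) {
      r2 <- stats::optim(r$par, fn = obj$fn, gr = obj$gr,
                         method = "L-BFGS-B", lower = lower,
                         control = list(maxit = maxit, factr = factr))
      if (r2$value > r$value + 1e-8) break
      r <- r2
      tries <- tries + 1L
    }
    r
  }
  res <- vector("list", n_starts)
  for (s in seq_len(n_starts)) {
    res[[s]] <- tryCatch(run1(starts[s, ]), error = function(e) e)
  }
  ok <- !vapply(res, inherits, logical(1), "error")
  conv <- vapply(res, function(r) if (inherits(r, "error")) NA_integer_
                 else r$convergence, integer(1))
  ll <- vapply(res, function(r) if (inherits(r, "error")) NA_real_
               else -r$value, numeric(1))
  converged <- ok & conv %in% c(0L, 1L)
  per_start <- tibble::tibble(start = seq_len(n_starts), loglik = ll,
                              convergence = conv, converged = converged)
  if (!any(converged)) {
    stop(paste0("no optimizer start converged; per-start diagnostics:\n",
                paste(utils::capture.output(print(as.data.frame(per_start))),
                      collapse = "\n")), call. = FALSE)
  }
  best <- which(converged)[which.max(ll[converged])]
  par <- res[[best]]$par
  sp <- split_par(par, md$n_participants)
  V <- recon_V(sp, md$flank_fixed)
  participants <- lapply(seq_len(md$n_participants),
                         function(i) opt_to_participant(V[i, ]))
  names(participants) <- md$participants
  structure(list(group = opt_to_group(c(sp$mu, sp$eta, sp$mu_lapse)),
                 participants = participants,
                 loglik = ll[best],
                 per_start = per_start,
                 n_starts = n_starts,
                 par = par,
                 seed = seed,
                 model_data = md),
            class = "recal_fit")
}

#' @export
print.recal_fit <- function(x, ...) {
  cat("Multilevel observer-model fit\n")
  cat(sprintf("  participants: %d   cells: %d   free parameters: %d\n",
              x$model_data$n_participants, length(x$model_data$cells$n),
              length(x$par)))
  cat(sprintf("  joint log-likelihood: %.2f (best of %d starts, %d converged)\n",
              x$loglik, x$n_starts, sum(x$per_start$converged)))
  g <- x$group
  cat(sprintf("  group: tau_bar %.1f ms (sd %.1f), delta_bar %.1f ms (log-sd %.2f)\n",
              g$tau_bar[1], g$tau_bar[2], exp(g$delta_bar[1]), g$delta_bar[2]))
  invisible(x)
}

# Box constraints for the optimizer: unconstrained everywhere except the
# group log-sd coordinates, bounded below so a collapsing group sd stops
# at the floor instead of crawling towards -Inf with vanishing gradient.
par_lower <- function(np) {
  k <- length(.GRP_COLS)
  lower <- rep(-Inf, .N_IND * np + 2 * k + 1)
  lower[.N_IND * np + k + seq_len(k)] <- log(.SD_FLOOR)
  lower
}

# Internal single- or few-start refit used by resampling procedures:
# warm-starts from an existing parameter vector and accepts the result
# as long as the optimizer finishes.
refit_from <- function(md, par0, maxit = 200, factr = 1e8) {
  lower <- par_lower(md$n_participants)
  obj <- make_objective(md)
  r <- stats::optim(pmax(par0, lower), fn = obj$fn, gr = obj$gr,
                    method = "L-BFGS-B", lower = lower,
                    control = list(maxit = maxit, factr = factr))
  list(par = r$par, loglik = -r$value, convergence = r$convergence)
}

#' Sensitivity of a fit to local optima
#'
#' Refits the model from additional jittered starts and reports the
#' spread of the attained joint log-likelihood and of the headline
#' adaptation effects (overall and per task x modality cell, in ms)
#' across local optima.
#'
#' @param fit a [fit_observer_model()] result.
#' @param n_starts_validation number of extra starts (default 50).
#' @param seed seed for the validation starts.
#' @param maxit,factr optimizer controls for the validation refits.
#' @return list with `loglik` (per-start values), `loglik_spread`
#'   (max - min), and `effect_spread` (tibble: effect, min, max, spread
#'   in ms across starts).
#' @export
stability_check <- function(fit, n_starts_validation = 50, seed = 1,
                            maxit = 2000, factr = 1e7) {
  md <- fit$model_data
  starts <- initial_values(md, seed = seed, n_starts = n_starts_validation)
  lls <- numeric(n_starts_validation)
  effs <- vector("list", n_starts_validation)
  for (s in seq_len(n_starts_validation)) {
    r <- refit_from(md, starts[s, ], maxit = maxit, factr = factr)
    lls[s] <- r$loglik
    et <- effect_table_from_par(r$par, md)
    effs[[s]] <- et$estimate[et$parameter == "tau" &
                               et$effect == "adaptation"]
  }
  E <- do.call(rbind, effs)
  et0 <- effect_table(fit)
  nm <- et0$cell[et0$parameter == "tau" & et0$effect == "adaptation"]
  nm[is.na(nm)] <- "overall"
  list(loglik = lls,
       loglik_spread = max(lls) - min(lls),
       effect_spread = tibble::tibble(effect = paste("adaptation", nm),
                                      min = apply(E, 2, min),
                                      max = apply(E, 2, max),
                                      spread_ms = apply(E, 2, max) -
                                        apply(E, 2, min)))
}
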