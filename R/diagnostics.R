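#' Overdispersion value for one participant
#'
#' Posterior-predictive-style check at the (penalized) MLE: the observed
#' data's log-likelihood under the fitted cell probabilities is compared
#' against `n_draws` replicate datasets simulated from those same
#' binomial probabilities. The value is the proportion of replicates
#' whose likelihood exceeds the observed one (ties count as not-lower).
#' Around 0.5 when the binomial model holds; values above 0.95 indicate
#' significant overdispersion.
#'
#' @param p a [participant_params()] object (typically fitted).
#' @param cells the participant's aggregated cells (columns `task`,
#'   `modality`, `lag`, `rsa_ms`, `n_trials`, `n_yes`).
#' @param n_draws number of replicate draws (default 1000).
#' @param seed RNG seed.
#' @return proportion in \[0, 1\].
#' @export
overdispersion_value <- function(p, cells, n_draws = 1000, seed = NULL) {
  if (n_draws < 1) stop("n_draws must be >= 1", call. = FALSE)
  pr <- predicted_probabilities(p, cells)
  n <- cells$n_trials
  l_obs <- sum(stats::dbinom(cells$n_yes, n, pr, log = TRUE))
  k <- length(pr)
  with_seed(seed, {
    yr <- matrix(stats::rbinom(k * n_draws, n, pr), nrow = k)
    l_rep <- colSums(stats::dbinom(yr, n, pr, log = TRUE))
    mean(l_obs < l_rep)
  })
}

#' Per-participant overdispersion report
#'
#' Applies [overdispersion_value()] to every participant of a fit.
#'
#' @param fit a [fit_observer_model()] result.
#' @param table the aggregated binomial table the fit was computed on.
#' @param n_draws replicate draws per participant (default 1000).
#' @param seed master seed (fanned out per participant).
#' @param flag_above flag threshold (default 0.95).
#' @return tibble with `participant_id`, `value`, `flag`; group mean and
#'   sd, `n_draws` and `seed` attached as attributes.
#' @export
overdispersion_check <- function(fit, table, n_draws = 1000, seed = 1,
                                 flag_above = 0.95) {
  stopifnot(inherits(fit, "recal_fit"))
  ids <- fit$model_data$participants
  vals <- vapply(seq_along(ids), function(i) {
    cells <- table[table$participant_id == ids[i], , drop = FALSE]
    overdispersion_value(fit$participants[[i]], cells,
                         n_draws = n_draws, seed = fan_seed(seed, i))
  }, numeric(1))
  out <- tibble::tibble(participant_id = ids, value = vals,
                        flag = vals > flag_above)
  attr(out, "summary") <- c(mean = mean(vals), sd = stats::sd(vals))
  attr(out, "n_draws") <- n_draws
  attr(out, "seed") <- seed
  out
}
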