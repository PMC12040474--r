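#' Effects codes for a design cell
#'
#' Maps the factor levels of one design cell to effects codes. The fixed
#' convention is simultaneity/visual/lag0 -> -0.5 and
#' agency/auditory/lag150 -> +0.5, so every reported effect reads as
#' (+0.5 level) minus (-0.5 level): a positive adaptation effect on the
#' psychometric midpoint is a rightward (stimulus-lagging) shift.
#'
#' @param task `"simultaneity"` or `"agency"`.
#' @param modality `"visual"` or `"auditory"`.
#' @param lag `"lag0"` or `"lag150"`.
#' @return named numeric vector with elements `t`, `s`, `a`.
#' @examples
#' effects_code("simultaneity", "visual", "lag0")   # all -0.5
#' @export
effects_code <- function(task, modality, lag) {
  code1 <- function(x, levels, what) {
    i <- match(x, levels)
    if (is.na(i)) {
      stop(sprintf("unknown %s level: '%s' (expected %s)",
                   what, x, paste(levels, collapse = " or ")), call. = FALSE)
    }
    c(-0.5, 0.5)[i]
  }
  c(t = code1(task, .TASKS, "task"),
    s = code1(modality, .MODALITIES, "modality"),
    a = code1(lag, .LAGS, "lag"))
}

# The 8 design cells in canonical order, with their effects-code design
# matrix (columns: t, s, a, ts, ta, sa, tsa).
condition_grid <- function() {
  g <- expand.grid(task = .TASKS, modality = .MODALITIES, lag = .LAGS,
                   stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  tibble::as_tibble(g[, c("task", "modality", "lag")])
}

code_matrix <- function() {
  g <- condition_grid()
  t <- ifelse(g$task == .TASKS[2], 0.5, -0.5)
  s <- ifelse(g$modality == .MODALITIES[2], 0.5, -0.5)
  a <- ifelse(g$lag == .LAGS[2], 0.5, -0.5)
  X <- cbind(t, s, a, t * s, t * a, s * a, t * s * a)
  colnames(X) <- .EFFECT_NAMES
  X
}

#' Construct participant-level parameters
#'
#' Bundles the 33 free scalars describing one participant: grand-mean
#' psychometric midpoint `tau_bar` (ms), criterion separation `delta_bar`
#' (ms, > 0), left-flank noise `sigmaL_bar` (ms, > 0), log flank-noise
#' ratio `m_bar`, half lapse rate `lapse` in \[0, 0.5), and four vectors
#' of 7 effects-coded coefficients (order: task, modality, adaptation,
#' task:modality, task:adaptation, modality:adaptation,
#' task:modality:adaptation). `beta_tau` is additive in ms;
#' `beta_delta` and `beta_sigma` act multiplicatively through `exp()`;
#' `beta_m` is additive on the log-ratio scale.
#'
#' @param tau_bar,delta_bar,sigmaL_bar,m_bar,lapse scalars as above.
#' @param beta_tau,beta_delta,beta_sigma,beta_m numeric length-7 vectors.
#' @return object of class `participant_params`.
#' @export
participant_params <- function(tau_bar = 150, delta_bar = 311,
                               sigmaL_bar = 70, m_bar = 0, lapse = 0.02,
                               beta_tau = numeric(7), beta_delta = numeric(7),
                               beta_sigma = numeric(7), beta_m = numeric(7)) {
  stopifnot(delta_bar > 0, sigmaL_bar > 0, lapse >= 0, lapse < 0.5,
            length(beta_tau) == 7, length(beta_delta) == 7,
            length(beta_sigma) == 7, length(beta_m) == 7)
  structure(list(tau_bar = tau_bar, delta_bar = delta_bar,
                 sigmaL_bar = sigmaL_bar, m_bar = m_bar, lapse = lapse,
                 beta_tau = stats::setNames(as.numeric(beta_tau), .EFFECT_NAMES),
                 beta_delta = stats::setNames(as.numeric(beta_delta), .EFFECT_NAMES),
                 beta_sigma = stats::setNames(as.numeric(beta_sigma), .EFFECT_NAMES),
                 beta_m = stats::setNames(as.numeric(beta_m), .EFFECT_NAMES)),
            class = "participant_params")
}

#' Condition-specific psychometric parameters
#'
#' Evaluates the effects-coded predictors for one design cell: the
#' midpoint is additive, criterion separation and left-flank noise are
#' multiplicative (exp of a linear predictor, guaranteeing positivity),
#' and the log flank-noise ratio is additive. Interactions enter through
#' products of codes, so a two-way coefficient equals the
#' difference-of-differences of cell values.
#'
#' @param p a [participant_params()] object.
#' @param code an [effects_code()] vector (elements `t`, `s`, `a`).
#' @return list with `tau`, `delta`, `sigmaL` (ms) and `m`.
#' @export
condition_params <- function(p, code) {
  x <- c(code[["t"]], code[["s"]], code[["a"]],
         code[["t"]] * code[["s"]], code[["t"]] * code[["a"]],
         code[["s"]] * code[["a"]], code[["t"]] * code[["s"]] * code[["a"]])
  list(tau    = p$tau_bar + sum(x * p$beta_tau),
       delta  = p$delta_bar * exp(sum(x * p$beta_delta)),
       sigmaL = p$sigmaL_bar * exp(sum(x * p$beta_sigma)),
       m      = p$m_bar + sum(x * p$beta_m))
}

#' Probability that an asynchrony falls inside the decision window
#'
#' Two-criterion psychometric function: the subjective asynchrony is
#' judged "inside" when it exceeds the low criterion (at
#' `tau - delta/2`, Gaussian noise sd `sigmaL`) but not the high
#' criterion (at `tau + delta/2`, noise sd `exp(m) * sigmaL`). With
#' unequal flank noise the difference of the two normal CDFs can dip
#' slightly below zero in the far tails; it is floored at 0 so the
#' result is always a valid probability.
#'
#' @param rsa response-stimulus asynchrony in ms (vectorized).
#' @param cp list with `tau`, `delta`, `sigmaL`, `m`
#'   (see [condition_params()]).
#' @return probability in \[0, 1\], same length as `rsa`.
#' @examples
#' detection_probability(0, list(tau = 0, delta = 2, sigmaL = 1, m = 0))
#' @export
detection_probability <- function(rsa, cp) {
  z1 <- (rsa - (cp$tau - cp$delta / 2)) / cp$sigmaL
  z2 <- (rsa - (cp$tau + cp$delta / 2)) / (exp(cp$m) * cp$sigmaL)
  pmax(stats::pnorm(z1) - stats::pnorm(z2), 0)
}

#' Lapse-mixed response probability
#'
#' Mixes the detection probability with guessing: with probability `2l`
#' the participant is distracted and responds yes with probability 1/2,
#' so the yes-probability is `l + p - 2*l*p`, confined to
#' \[`l`, `1 - l`\].
#'
#' @param p detection probability in \[0, 1\] (vectorized).
#' @param lapse half the lapse rate, in \[0, 0.5).
#' @return response probability.
#' @export
response_probability <- function(p, lapse) {
  lapse + p - 2 * lapse * p
}

#' Binomial log-likelihood of one participant's data
#'
#' Sums the binomial log-pmf over a participant's aggregated cells using
#' the lapse-mixed two-criterion model. With a zero lapse a cell whose
#' predicted probability is exactly 0 (or 1) and whose data contradict
#' it yields `-Inf` (returned, not thrown).
#'
#' @param p a [participant_params()] object.
#' @param cells data frame with columns `task`, `modality`, `lag`,
#'   `rsa_ms`, `n_trials`, `n_yes` (one participant's cells).
#' @return total log-likelihood (scalar).
#' @export
participant_loglik <- function(p, cells) {
  pr <- predicted_probabilities(p, cells)
  ll <- stats::dbinom(cells$n_yes, cells$n_trials, pr, log = TRUE)
  if (any(!is.finite(ll))) {
    message("participant_loglik: predicted probability 0 or 1 contradicted ",
            "by data; returning -Inf")
    return(-Inf)
  }
  sum(ll)
}

# Lapse-mixed predicted yes-probability for each row of a cell table.
predicted_probabilities <- function(p, cells) {
  pr <- numeric(nrow(cells))
  key <- paste(cells$task, cells$modality, cells$lag)
  for (k in unique(key)) {
    i <- which(key == k)
    cd <- effects_code(cells$task[i[1]], cells$modality[i[1]], cells$lag[i[1]])
    cp <- condition_params(p, cd)
    pr[i] <- response_probability(detection_probability(cells$rsa_ms[i], cp),
                                  p$lapse)
  }
  pr
}

#' Joint penalized log-likelihood of the multilevel model
#'
#' The objective maximized by [fit_observer_model()]: the sum of all
#' participants' binomial log-likelihoods plus, for every participant,
#' the log group density of each of their 33 parameters under the
#' group-level distributions (Gaussian on the identity scale for the
#' midpoint, flank-ratio and all coefficients; Gaussian on the log scale
#' for criterion separation and left-flank noise; for the lapse, a
#' logit-scale Gaussian with fixed sd whose mean is the single free
#' group lapse scalar).
#'
#' @param group a [group_params()] object.
#' @param participants list of [participant_params()], one per
#'   participant in `table`, in the order of
#'   `sort(unique(table$participant_id))`.
#' @param table aggregated binomial table (see [aggregate_trials()]).
#' @return scalar log-likelihood.
#' @export
joint_log_likelihood <- function(group, participants, table) {
  md <- as_model_data(table)
  if (length(participants) != md$n_participants) {
    stop("need exactly one participant_params per participant in `table`",
         call. = FALSE)
  }
  V <- do.call(rbind, lapply(participants, participant_to_opt))
  gv <- group_to_opt(group)
  k <- length(.GRP_COLS)
  par <- pack_par(V, gv[seq_len(k)], gv[k + seq_len(k)], gv[2 * k + 1])
  -joint_nll(par, md)
}
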