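#' Construct group-level parameters
#'
#' The 65 free group-level scalars of the multilevel model: a (mean, sd)
#' pair for each of the 32 non-lapse individual parameters — on the
#' identity (ms) scale for `tau_bar`, `m_bar` and the `beta_tau`
#' coefficients, and on the log scale (lognormal on the natural scale)
#' for `delta_bar` and `sigmaL_bar`; `beta_delta`, `beta_sigma` and
#' `beta_m` live on their natural (unitless) scales — plus a single
#' lapse location. The lapse is modelled on the scaled-logit scale as a
#' Gaussian with free mean and fixed sd 0.5, so it contributes one free
#' scalar, giving 2 * 32 + 1 = 65.
#'
#' @param tau_bar c(mean, sd) in ms.
#' @param delta_bar c(meanlog, sdlog) of the lognormal for the
#'   criterion separation (ms on the natural scale).
#' @param sigmaL_bar c(meanlog, sdlog) for the left-flank noise.
#' @param m_bar c(mean, sd), unitless.
#' @param lapse typical half lapse rate in (1e-4, 0.5); stored as the
#'   mean of the scaled-logit Gaussian.
#' @param beta_tau,beta_delta,beta_sigma,beta_m 7 x 2 matrices
#'   (columns mean, sd; rows in the effect order task, modality,
#'   adaptation and their interactions).
#' @return object of class `group_params`.
#' @seealso [group_preset()] for ready-made settings.
#' @export
group_params <- function(tau_bar = c(150, 70),
                         delta_bar = c(log(311), 0.30),
                         sigmaL_bar = c(log(70), 0.40),
                         m_bar = c(0, 0.30),
                         lapse = 0.03,
                         beta_tau = beta_block(),
                         beta_delta = beta_block(),
                         beta_sigma = beta_block(),
                         beta_m = beta_block()) {
  chk2 <- function(x, nm) {
    if (length(x) != 2 || x[2] < 0)
      stop(sprintf("`%s` must be c(mean, sd >= 0)", nm), call. = FALSE)
    as.numeric(x)
  }
  chkb <- function(b, nm) {
    b <- as.matrix(b)
    if (!all(dim(b) == c(7, 2)) || any(b[, 2] < 0))
      stop(sprintf("`%s` must be a 7 x 2 (mean, sd) matrix", nm), call. = FALSE)
    dimnames(b) <- list(.EFFECT_NAMES, c("mean", "sd"))
    b
  }
  stopifnot(lapse > .LAPSE_LO, lapse < .LAPSE_HI)
  structure(list(tau_bar = chk2(tau_bar, "tau_bar"),
                 delta_bar = chk2(delta_bar, "delta_bar"),
                 sigmaL_bar = chk2(sigmaL_bar, "sigmaL_bar"),
                 m_bar = chk2(m_bar, "m_bar"),
                 lapse = as.numeric(lapse),
                 beta_tau = chkb(beta_tau, "beta_tau"),
                 beta_delta = chkb(beta_delta, "beta_delta"),
                 beta_sigma = chkb(beta_sigma, "beta_sigma"),
                 beta_m = chkb(beta_m, "beta_m")),
            class = "group_params")
}

#' Build a 7 x 2 coefficient block
#'
#' Convenience constructor for the (mean, sd) matrix of one family of
#' effects-coded coefficients. Named arguments set individual rows;
#' unset rows default to `mean0`/`sd0`.
#'
#' @param ... named `c(mean, sd)` entries, names among
#'   `"task"`, `"modality"`, `"adaptation"`, `"task:modality"`,
#'   `"task:adaptation"`, `"modality:adaptation"`,
#'   `"task:modality:adaptation"`.
#' @param mean0,sd0 defaults for unset rows.
#' @export
beta_block <- function(..., mean0 = 0, sd0 = 0) {
  b <- matrix(c(rep(mean0, 7), rep(sd0, 7)), 7, 2,
              dimnames = list(.EFFECT_NAMES, c("mean", "sd")))
  dots <- list(...)
  for (nm in names(dots)) {
    if (!nm %in% .EFFECT_NAMES)
      stop("unknown effect name: ", nm, call. = FALSE)
    b[nm, ] <- as.numeric(dots[[nm]])
  }
  b
}

#' Named generating presets for the synthetic-data module
#'
#' `"paper-like"` reflects headline group estimates from the study the
#' model emulates: grand-mean midpoint 150 ms, lognormal criterion
#' separation centred at 311 ms, a 34 ms adaptation shift and 51 ms
#' modality shift of the midpoint, and a wider yes-window (about +36 ms)
#' for auditory test stimuli; remaining coefficient means are 0.
#' Between-participant spreads are set so the implied standardized
#' effect sizes are of the order reported for those effects.
#' `"null"` keeps the same grand means but zeroes every coefficient
#' (mean and sd), giving data in which condition labels are exchangeable
#' within participant — the reference case for permutation-test
#' calibration.
#'
#' @param name `"paper-like"` or `"null"`.
#' @return a [group_params()] object.
#' @export
group_preset <- function(name = c("paper-like", "null")) {
  name <- match.arg(name)
  base <- list(tau_bar = c(150, 70), delta_bar = c(log(311), 0.30),
               sigmaL_bar = c(log(70), 0.40), m_bar = c(0, 0.30),
               lapse = 0.03)
  if (name == "null") {
    return(do.call(group_params, base))
  }
  # +36 ms modality effect on a 311 ms window, expressed on the log scale:
  # delta_bar * (exp(b/2) - exp(-b/2)) = 36  =>  b = 2 asinh(36 / (2*311))
  b_delta_s <- 2 * asinh(36 / (2 * 311))
  do.call(group_params, c(base, list(
    beta_tau = beta_block(task = c(0, 37), modality = c(51, 49),
                          adaptation = c(34, 32),
                          `task:modality` = c(0, 25),
                          `task:adaptation` = c(0, 25),
                          `modality:adaptation` = c(0, 25),
                          `task:modality:adaptation` = c(0, 25)),
    beta_delta = beta_block(modality = c(b_delta_s, 0.15), sd0 = 0.15),
    beta_sigma = beta_block(sd0 = 0.15),
    beta_m = beta_block(sd0 = 0.10))))
}

# ---- internal conversions between natural and optimizer scales --------

lapse_to_logit <- function(l) {
  stats::qlogis((l - .LAPSE_LO) / (.LAPSE_HI - .LAPSE_LO))
}

logit_to_lapse <- function(z) {
  .LAPSE_LO + (.LAPSE_HI - .LAPSE_LO) * stats::plogis(z)
}

# One participant_params -> length-33 optimizer-scale vector.
participant_to_opt <- function(p) {
  v <- numeric(.N_IND)
  v[.I_TAU]    <- p$tau_bar / .MS_SCALE
  v[.I_DELTA]  <- log(p$delta_bar / .MS_SCALE)
  v[.I_SIGMA]  <- log(p$sigmaL_bar / .MS_SCALE)
  v[.I_M]      <- p$m_bar
  v[.I_LAPSE]  <- lapse_to_logit(max(p$lapse, .LAPSE_LO * 1.0001))
  v[.I_BTAU]   <- p$beta_tau / .MS_SCALE
  v[.I_BDELTA] <- p$beta_delta
  v[.I_BSIGMA] <- p$beta_sigma
  v[.I_BM]     <- p$beta_m
  v
}

opt_to_participant <- function(v) {
  participant_params(tau_bar = v[.I_TAU] * .MS_SCALE,
                     delta_bar = exp(v[.I_DELTA]) * .MS_SCALE,
                     sigmaL_bar = exp(v[.I_SIGMA]) * .MS_SCALE,
                     m_bar = v[.I_M],
                     lapse = logit_to_lapse(v[.I_LAPSE]),
                     beta_tau = v[.I_BTAU] * .MS_SCALE,
                     beta_delta = v[.I_BDELTA],
                     beta_sigma = v[.I_BSIGMA],
                     beta_m = v[.I_BM])
}

# group_params -> length-65 vector c(mu[32], eta[32], mu_lapse), where
# mu/eta refer to the optimizer scale of the corresponding individual
# parameter columns (.GRP_COLS) and sd = .SD_FLOOR + exp(eta).
group_to_opt <- function(g) {
  mu <- sg <- numeric(length(.GRP_COLS))
  put <- function(col, mean, sd) {
    i <- match(col, .GRP_COLS)
    mu[i] <<- mean
    sg[i] <<- sd
  }
  put(.I_TAU, g$tau_bar[1] / .MS_SCALE, g$tau_bar[2] / .MS_SCALE)
  put(.I_DELTA, g$delta_bar[1] - log(.MS_SCALE), g$delta_bar[2])
  put(.I_SIGMA, g$sigmaL_bar[1] - log(.MS_SCALE), g$sigmaL_bar[2])
  put(.I_M, g$m_bar[1], g$m_bar[2])
  for (j in 1:7) {
    put(.I_BTAU[j], g$beta_tau[j, 1] / .MS_SCALE, g$beta_tau[j, 2] / .MS_SCALE)
    put(.I_BDELTA[j], g$beta_delta[j, 1], g$beta_delta[j, 2])
    put(.I_BSIGMA[j], g$beta_sigma[j, 1], g$beta_sigma[j, 2])
    put(.I_BM[j], g$beta_m[j, 1], g$beta_m[j, 2])
  }
  eta <- log(pmax(sg - .SD_FLOOR, 1e-12))
  c(mu, eta, lapse_to_logit(g$lapse))
}

opt_to_group <- function(gv) {
  k <- length(.GRP_COLS)
  mu <- gv[seq_len(k)]
  sg <- .SD_FLOOR + exp(gv[k + seq_len(k)])
  get2 <- function(col) {
    i <- match(col, .GRP_COLS)
    c(mu[i], sg[i])
  }
  bt <- bd <- bs <- bm <- matrix(0, 7, 2)
  for (j in 1:7) {
    bt[j, ] <- get2(.I_BTAU[j]) * .MS_SCALE
    bd[j, ] <- get2(.I_BDELTA[j])
    bs[j, ] <- get2(.I_BSIGMA[j])
    bm[j, ] <- get2(.I_BM[j])
  }
  td <- get2(.I_DELTA); ts <- get2(.I_SIGMA)
  group_params(tau_bar = get2(.I_TAU) * .MS_SCALE,
               delta_bar = c(td[1] + log(.MS_SCALE), td[2]),
               sigmaL_bar = c(ts[1] + log(.MS_SCALE), ts[2]),
               m_bar = get2(.I_M),
               lapse = logit_to_lapse(gv[2 * k + 1]),
               beta_tau = bt, beta_delta = bd, beta_sigma = bs, beta_m = bm)
}
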