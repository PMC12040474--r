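# Internal representation of an aggregated binomial table, indexed for
# the vectorized likelihood: integer participant and condition indices
# per cell, the 8 x 7 effects-code matrix, and cached constants.

as_model_data <- function(table) {
  if (inherits(table, "recal_model_data")) return(table)
  stopifnot(all(c("participant_id", "task", "modality", "lag", "rsa_ms",
                  "n_trials", "n_yes") %in% names(table)))
  if (nrow(table) == 0) stop("empty binomial table", call. = FALSE)
  if (any(table$n_yes > table$n_trials) || any(table$n_yes < 0)) {
    stop("invalid counts: need 0 <= n_yes <= n_trials", call. = FALSE)
  }
  grid <- condition_grid()
  pid <- sort(unique(table$participant_id))
  p <- match(table$participant_id, pid)
  cond <- match(paste(table$task, table$modality, table$lag),
                paste(grid$task, grid$modality, grid$lag))
  if (anyNA(cond)) {
    bad <- which(is.na(cond))[1]
    stop(sprintf("unknown condition levels in row %d: %s/%s/%s", bad,
                 table$task[bad], table$modality[bad], table$lag[bad]),
         call. = FALSE)
  }
  np <- length(pid)
  # participants whose data cannot identify flank parameters
  n_rsa <- tapply(table$rsa_ms, p, function(x) length(unique(x)))
  flank_fixed <- as.integer(names(n_rsa))[n_rsa < 2]
  structure(list(
    participants = pid,
    n_participants = np,
    cells = list(p = p, cond = cond, rsa = as.numeric(table$rsa_ms),
                 n = as.numeric(table$n_trials),
                 y = as.numeric(table$n_yes)),
    idx = cbind(p, cond),             # matrix index into np x 8 matrices
    blk = p + (cond - 1L) * np,       # column-major block id
    X = code_matrix(),
    lchoose_sum = sum(lchoose(table$n_trials, table$n_yes)),
    flank_fixed = flank_fixed,
    grid = grid
  ), class = "recal_model_data")
}

# Parameter-vector storage is non-centered: the individual block holds
# z-scores Zc with V[, q] = mu[q] + sigma[q] * Zc[, q] for the 32
# group-distributed columns (the lapse column 5 is stored directly),
# followed by the group means mu[32], log-sds eta[32] (sd = floor +
# exp(eta)) and the group lapse location.  The non-centered form keeps
# the penalty isotropic so L-BFGS does not stall when a group sd
# collapses to the floor.
split_par <- function(par, np) {
  k <- length(.GRP_COLS)
  list(Zc = matrix(par[seq_len(.N_IND * np)], np, .N_IND),
       mu = par[.N_IND * np + seq_len(k)],
       eta = par[.N_IND * np + k + seq_len(k)],
       mu_lapse = par[.N_IND * np + 2 * k + 1])
}

group_sds <- function(eta) .SD_FLOOR + exp(eta)

# Reconstruct the optimizer-scale participant matrix V from a split
# parameter vector, pinning unidentifiable flank columns (z = 0, i.e.
# the group mean).
recon_V <- function(sp, flank_fixed = integer(0)) {
  Zc <- sp$Zc
  if (length(flank_fixed) > 0) Zc[flank_fixed, .FLANK_COLS] <- 0
  sg <- group_sds(sp$eta)
  V <- Zc
  V[, .GRP_COLS] <- sweep(sweep(Zc[, .GRP_COLS, drop = FALSE], 2, sg, "*"),
                          2, sp$mu, "+")
  V
}

# Full parameter vector from an optimizer-scale V matrix plus group
# block (inverse of recon_V on the free coordinates).
pack_par <- function(V, mu, eta, mu_lapse) {
  sg <- group_sds(eta)
  Zc <- V
  Zc[, .GRP_COLS] <- sweep(sweep(V[, .GRP_COLS, drop = FALSE], 2, mu),
                           2, sg, "/")
  c(as.vector(Zc), mu, eta, mu_lapse)
}

# Natural-scale condition-parameter matrices (n_participants x 8) from
# the optimizer-scale participant matrix.
condition_matrices <- function(V, X) {
  tXt <- t(X)
  # clamp log-scale linear predictors so stray line-search steps cannot
  # overflow exp(); the group penalty (which acts on the z-scores, not
  # through these values) still pulls the parameters back
  clamp <- function(x) pmin(pmax(x, -15), 15)
  list(Tau = .MS_SCALE * (V[, .I_TAU] + V[, .I_BTAU, drop = FALSE] %*% tXt),
       Del = .MS_SCALE * exp(clamp(V[, .I_DELTA] +
                                     V[, .I_BDELTA, drop = FALSE] %*% tXt)),
       Sig = .MS_SCALE * exp(clamp(V[, .I_SIGMA] +
                                     V[, .I_BSIGMA, drop = FALSE] %*% tXt)),
       M = clamp(V[, .I_M] + V[, .I_BM, drop = FALSE] %*% tXt),
       lapse = logit_to_lapse(V[, .I_LAPSE]))
}

# Per-cell predicted yes-probability plus the intermediates the gradient
# needs.  Returns a list of vectors aligned with md$cells.
cell_probabilities <- function(V, md) {
  cm <- condition_matrices(V, md$X)
  idx <- md$idx
  tau <- cm$Tau[idx]; del <- cm$Del[idx]
  sig <- cm$Sig[idx]; m <- cm$M[idx]
  sigR <- exp(m) * sig
  dt <- md$cells$rsa
  z1 <- (dt - (tau - del / 2)) / sig
  z2 <- (dt - (tau + del / 2)) / sigR
  p0 <- stats::pnorm(z1) - stats::pnorm(z2)
  p <- pmax(p0, 0)
  lp <- cm$lapse[md$cells$p]
  list(cm = cm, tau = tau, del = del, sig = sig, sigR = sigR,
       z1 = z1, z2 = z2, p0 = p0, p = p, lp = lp,
       r = lp + p - 2 * lp * p)
}

# Negative joint penalized log-likelihood (the optimizer objective).
# The penalty value equals the sum of log group densities of the
# individual parameters: in non-centered coordinates
# log N(v; mu, sg) = -z^2/2 - log(sg) - log(2*pi)/2 with z = (v-mu)/sg.
joint_nll <- function(par, md, lapse_sd = .LAPSE_SD) {
  np <- md$n_participants
  sp <- split_par(par, np)
  Zc <- sp$Zc
  if (length(md$flank_fixed) > 0) Zc[md$flank_fixed, .FLANK_COLS] <- 0
  V <- recon_V(sp, md$flank_fixed)
  cp <- cell_probabilities(V, md)
  ll <- md$lchoose_sum +
    sum(md$cells$y * log(cp$r) + (md$cells$n - md$cells$y) * log1p(-cp$r))
  sg <- group_sds(sp$eta)
  Z <- Zc[, .GRP_COLS, drop = FALSE]
  pen <- -np * sum(log(sg)) - np * length(sg) * 0.5 * log(2 * pi) -
    sum(Z^2) / 2
  pen <- pen + sum(stats::dnorm(V[, .I_LAPSE], sp$mu_lapse, lapse_sd,
                                log = TRUE))
  -(ll + pen)
}

# Memoizing objective factory: L-BFGS-B evaluates fn and gr in pairs at
# the same point, so value and gradient are computed in one forward
# pass and cached for the matching call.
make_objective <- function(md, lapse_sd = .LAPSE_SD) {
  last <- NULL
  cache <- NULL
  ensure <- function(par) {
    if (is.null(last) || !identical(par, last)) {
      cache <<- joint_gr(par, md, lapse_sd, value_too = TRUE)
      last <<- par
    }
  }
  list(fn = function(par) {
         ensure(par)
         cache$value
       },
       gr = function(par) {
         ensure(par)
         cache$grad
       })
}

# Analytic gradient of joint_nll (shares its forward pass; with
# value_too = TRUE also returns the objective value).
joint_gr <- function(par, md, lapse_sd = .LAPSE_SD, value_too = FALSE) {
  np <- md$n_participants
  sp <- split_par(par, np)
  Zc <- sp$Zc
  if (length(md$flank_fixed) > 0) Zc[md$flank_fixed, .FLANK_COLS] <- 0
  V <- recon_V(sp, md$flank_fixed)
  cp <- cell_probabilities(V, md)
  cl <- md$cells

  dll_dr <- cl$y / cp$r - (cl$n - cl$y) / (1 - cp$r)
  live <- as.numeric(cp$p0 > 0)          # flooring blocks the gradient
  gp <- dll_dr * (1 - 2 * cp$lp) * live  # d loglik / d p0
  phi1 <- stats::dnorm(cp$z1)
  phi2 <- stats::dnorm(cp$z2)

  g_tau_c <- gp * (-phi1 / cp$sig + phi2 / cp$sigR)
  g_del_c <- gp * 0.5 * (phi1 / cp$sig + phi2 / cp$sigR)
  g_sig_c <- gp * (-phi1 * cp$z1 + phi2 * cp$z2) / cp$sig
  g_m_c   <- gp * phi2 * cp$z2
  g_l_c   <- dll_dr * (1 - 2 * cp$p)

  # accumulate per participant x condition block (column-major key
  # matching the np x 8 matrices)
  blk <- md$blk
  acc <- function(x) {
    out <- numeric(np * 8L)
    s <- rowsum(x, blk)
    out[as.integer(rownames(s))] <- s
    matrix(out, np, 8L)
  }
  Gtau <- acc(g_tau_c)
  Gdel <- acc(g_del_c) * cp$cm$Del   # chain through delta = exp(...) scale
  Gsig <- acc(g_sig_c) * cp$cm$Sig
  Gm   <- acc(g_m_c)

  gV <- matrix(0, np, .N_IND)
  gV[, .I_TAU]    <- rowSums(Gtau) * .MS_SCALE
  gV[, .I_BTAU]   <- (Gtau %*% md$X) * .MS_SCALE
  gV[, .I_DELTA]  <- rowSums(Gdel)
  gV[, .I_BDELTA] <- Gdel %*% md$X
  gV[, .I_SIGMA]  <- rowSums(Gsig)
  gV[, .I_BSIGMA] <- Gsig %*% md$X
  gV[, .I_M]      <- rowSums(Gm)
  gV[, .I_BM]     <- Gm %*% md$X
  s <- stats::plogis(V[, .I_LAPSE])
  g_l_p <- numeric(np)
  sl <- rowsum(g_l_c, cl$p)
  g_l_p[as.integer(rownames(sl))] <- sl
  gV[, .I_LAPSE] <- g_l_p * (.LAPSE_HI - .LAPSE_LO) * s * (1 - s)

  # chain the data gradient on V into the non-centered coordinates:
  # dV/dz = sg, dV/dmu = 1, dV/deta = z * exp(eta); then add the
  # isotropic penalty gradient -z on the z-scores.
  sg <- group_sds(sp$eta)
  Z <- Zc[, .GRP_COLS, drop = FALSE]
  gD <- gV[, .GRP_COLS, drop = FALSE]

  gZ <- gV
  gZ[, .GRP_COLS] <- sweep(gD, 2, sg, "*") - Z
  zl <- V[, .I_LAPSE] - sp$mu_lapse
  gZ[, .I_LAPSE] <- gZ[, .I_LAPSE] - zl / lapse_sd^2
  if (length(md$flank_fixed) > 0) {
    gZ[md$flank_fixed, .FLANK_COLS] <- 0   # dead coordinates
  }

  g_mu <- colSums(gD)
  g_eta <- (colSums(gD * Z) - np / sg) * exp(sp$eta)
  g_mul <- sum(zl) / lapse_sd^2

  grad <- -c(as.vector(gZ), g_mu, g_eta, g_mul)
  if (!value_too) return(grad)

  ll <- md$lchoose_sum +
    sum(cl$y * log(cp$r) + (cl$n - cl$y) * log1p(-cp$r))
  pen <- -np * sum(log(sg)) - np * length(sg) * 0.5 * log(2 * pi) -
    sum(Z^2) / 2 +
    sum(stats::dnorm(V[, .I_LAPSE], sp$mu_lapse, lapse_sd, log = TRUE))
  list(value = -(ll + pen), grad = grad)
}
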