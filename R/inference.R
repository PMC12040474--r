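# Model data with condition labels permuted within each participant
# (each participant's 8 cell-blocks keep their RSA structure; only the
# assignment of condition labels to blocks is shuffled).
permute_md <- function(md, perms) {
  cond <- md$cells$cond
  for (i in seq_len(md$n_participants)) {
    sel <- md$cells$p == i
    cond[sel] <- perms[[i]][cond[sel]]
  }
  md$cells$cond <- cond
  md$idx <- cbind(md$cells$p, cond)
  md$blk <- md$cells$p + (cond - 1L) * md$n_participants
  md
}

# Model data for a bootstrap multiset of participants (indices with
# repetition); repeated participants become distinct copies.
resample_md <- function(md, idx) {
  keep <- lapply(seq_along(idx), function(j) which(md$cells$p == idx[j]))
  lens <- lengths(keep)
  rows <- unlist(keep)
  md$cells <- list(p = rep(seq_along(idx), lens),
                   cond = md$cells$cond[rows],
                   rsa = md$cells$rsa[rows],
                   n = md$cells$n[rows],
                   y = md$cells$y[rows])
  md$idx <- cbind(md$cells$p, md$cells$cond)
  md$blk <- md$cells$p + (md$cells$cond - 1L) * length(idx)
  md$n_participants <- length(idx)
  md$participants <- md$participants[idx]
  md$flank_fixed <- which(idx %in% md$flank_fixed)
  md$lchoose_sum <- sum(lchoose(md$cells$n, md$cells$y))
  md
}

# Reshuffle the individual-parameter block of a parameter vector to a
# new participant multiset, keeping the group block.
reindex_par <- function(par, np, idx) {
  sp <- split_par(par, np)
  c(as.vector(sp$Zc[idx, , drop = FALSE]), sp$mu, sp$eta, sp$mu_lapse)
}

# Shared engine: B refits under label permutation, returning the full
# effect-table estimate matrix (B x n_statistics).
permutation_null <- function(fit, B, seed, maxit = 200, factr = 1e8,
                             max_redraw_frac = 0.05) {
  md <- fit$model_data
  np <- md$n_participants
  et0 <- effect_table(fit)
  out <- matrix(NA_real_, B, nrow(et0))
  with_seed(seed, {
    redraws <- 0L
    max_redraws <- max(1L, ceiling(max_redraw_frac * B))
    b <- 1L
    while (b <= B) {
      perms <- lapply(seq_len(np), function(i) sample.int(8L))
      mdp <- permute_md(md, perms)
      r <- tryCatch(refit_from(mdp, fit$par, maxit = maxit, factr = factr),
                    error = function(e) e)
      if (inherits(r, "error")) {
        redraws <- redraws + 1L
        if (redraws > max_redraws) {
          stop("too many permutation refit failures (", redraws, ")",
               call. = FALSE)
        }
        message("permutation refit failed; redrawing: ",
                conditionMessage(r))
        next
      }
      out[b, ] <- effect_table_from_par(r$par, mdp)$estimate
      b <- b + 1L
    }
  })
  colnames(out) <- paste(et0$parameter, et0$effect,
                         ifelse(is.na(et0$cell), "overall", et0$cell))
  out
}

# Shared engine: B participant-bootstrap refits.
bootstrap_null <- function(fit, B, seed, maxit = 200, factr = 1e8) {
  md <- fit$model_data
  np <- md$n_participants
  if (np < 2) stop("bootstrap needs >= 2 participants", call. = FALSE)
  et0 <- effect_table(fit)
  out <- matrix(NA_real_, B, nrow(et0))
  with_seed(seed, {
    b <- 1L
    while (b <= B) {
      idx <- sample.int(np, replace = TRUE)
      if (length(unique(idx)) < 2) {
        message("bootstrap resample with < 2 unique participants; redrawing")
        next
      }
      mdb <- resample_md(md, idx)
      r <- refit_from(mdb, reindex_par(fit$par, np, idx),
                      maxit = maxit, factr = factr)
      out[b, ] <- effect_table_from_par(r$par, mdb)$estimate
      b <- b + 1L
    }
  })
  colnames(out) <- paste(et0$parameter, et0$effect,
                         ifelse(is.na(et0$cell), "overall", et0$cell))
  out
}

#' Permutation test for a fitted condition effect
#'
#' Tests the null hypothesis that condition labels are exchangeable
#' within participants: for each of `B` permutations the 8 condition
#' labels are reassigned to each participant's 8 cell-blocks
#' independently, the full model is refitted (warm-started from the
#' observed fit), and the statistic recomputed. Two-sided p-value with
#' add-one correction, `(1 + #{|null| >= |observed|}) / (B + 1)`, so the
#' smallest attainable value is `1/(B+1)`.
#'
#' @param fit a [fit_observer_model()] result.
#' @param parameter `"tau"` or `"delta"`.
#' @param effect effect name from [effect_table()].
#' @param cell `NA` for a marginal effect, or `"task:modality"` for a
#'   simple adaptation effect.
#' @param B number of permutations (default 999).
#' @param seed RNG seed.
#' @param maxit,factr optimizer controls for the warm refits.
#' @return list with `observed`, `p`, `null` (the B null values),
#'   `B`, `seed`.
#' @export
permutation_test <- function(fit, parameter = "tau", effect = "adaptation",
                             cell = NA_character_, B = 999, seed = 1,
                             maxit = 200, factr = 1e8) {
  if (B < 1) stop("B must be >= 1", call. = FALSE)
  et <- effect_table(fit)
  obs <- statistic_value(et, parameter, effect, cell)
  null <- permutation_null(fit, B, seed, maxit = maxit, factr = factr)
  key <- paste(parameter, effect, ifelse(is.na(cell), "overall", cell))
  nv <- null[, key]
  list(observed = obs,
       p = (1 + sum(abs(nv) >= abs(obs))) / (B + 1),
       null = nv, B = B, seed = seed)
}

#' Participant bootstrap for a fitted condition effect
#'
#' Resamples complete participants with replacement `B` times, refits
#' the model (warm-started from the observed fit), and summarizes the
#' statistic's sampling spread: SE is the sd across resamples and the
#' 95% CI is the normal-theory interval `observed +/- 1.96 * SE`.
#'
#' @inheritParams permutation_test
#' @param B number of bootstrap resamples (default 999).
#' @return list with `observed`, `se`, `ci` (length-2), `boot` (the B
#'   resampled values), `B`, `seed`.
#' @export
bootstrap_effect <- function(fit, parameter = "tau", effect = "adaptation",
                             cell = NA_character_, B = 999, seed = 1,
                             maxit = 200, factr = 1e8) {
  if (B < 1) stop("B must be >= 1", call. = FALSE)
  et <- effect_table(fit)
  obs <- statistic_value(et, parameter, effect, cell)
  null <- bootstrap_null(fit, B, seed, maxit = maxit, factr = factr)
  key <- paste(parameter, effect, ifelse(is.na(cell), "overall", cell))
  bv <- null[, key]
  se <- stats::sd(bv)
  list(observed = obs, se = se,
       ci = obs + c(-1.96, 1.96) * se,
       boot = bv, B = B, seed = seed)
}

#' Standardized effect size from a bootstrap SE
#'
#' `d = observed / (SE * sqrt(n))`: the bootstrap SE of a mean over `n`
#' participants times `sqrt(n)` estimates the between-participant sd of
#' the effect, so the ratio is a Cohen's d for the within-subject
#' effect.
#'
#' @param observed group-mean effect.
#' @param se participant-bootstrap standard error of the effect.
#' @param n number of participants.
#' @return unitless effect size (NA with a message when `se` is 0).
#' @export
cohens_d <- function(observed, se, n) {
  if (!is.finite(se) || se <= 0) {
    message("cohens_d: SE is zero or non-finite; returning NA")
    return(NA_real_)
  }
  observed / (se * sqrt(n))
}

#' Classify a p-value against the marginal band
#'
#' With 999 permutations the 95% CI around p = 0.05 has half-width
#' about 0.014, so p-values in \[0.036, 0.064\] are classed as
#' `"marginal"`; below the band `"significant"`, above
#' `"nonsignificant"`.
#'
#' @param p p-value(s) in (0, 1].
#' @return character vector of classes.
#' @export
classify_significance <- function(p) {
  stopifnot(all(p > 0 & p <= 1))
  ifelse(p < 0.036, "significant",
         ifelse(p <= 0.064, "marginal", "nonsignificant"))
}

#' Half-width of the binomial 95% CI around a permutation p-value
#'
#' `1.96 * sqrt(p * (1 - p) / B)` — the Monte-Carlo uncertainty of a
#' p-value estimated from `B` permutations.
#'
#' @param p p-value in (0, 1).
#' @param B number of permutations.
#' @return half-width (probability units).
#' @examples
#' round(pvalue_ci_halfwidth(0.05, 999), 3)  # 0.014
#' @export
pvalue_ci_halfwidth <- function(p, B) {
  stopifnot(p > 0, p < 1, B >= 1)
  1.96 * sqrt(p * (1 - p) / B)
}

#' Minimum sample size for a paired/one-sample t-test
#'
#' Smallest `n` such that a two-sided (or one-sided) one-sample t-test
#' at level `alpha` attains the target power against a standardized
#' effect `d`, computed from the noncentral t distribution by iterating
#' `n` upward.
#'
#' @param d standardized effect size (> 0).
#' @param alpha significance level.
#' @param power target power.
#' @param two_sided logical (default TRUE).
#' @param n_max search cap.
#' @return integer sample size.
#' @examples
#' minimum_sample_size(0.5, 0.05, 0.90)  # 44
#' @export
minimum_sample_size <- function(d, alpha = 0.05, power = 0.90,
                                two_sided = TRUE, n_max = 1e6) {
  stopifnot(d > 0, alpha > 0, alpha < 1, power > 0, power < 1)
  a <- if (two_sided) alpha / 2 else alpha
  for (n in 2:n_max) {
    df <- n - 1
    tc <- stats::qt(1 - a, df)
    ncp <- d * sqrt(n)
    pw <- stats::pt(tc, df, ncp = ncp, lower.tail = FALSE)
    if (two_sided) pw <- pw + stats::pt(-tc, df, ncp = ncp)
    if (pw >= power) return(n)
  }
  stop("target power unattainable within n_max", call. = FALSE)
}

#' Permutation and bootstrap inference for the full effect family
#'
#' Runs the permutation test and participant bootstrap once, sharing the
#' `B_perm` permutation refits and `B_boot` bootstrap refits across all
#' rows of the [effect_table()], and attaches SE, 95% CI, Cohen's d,
#' p-value and significance class to every effect.
#'
#' @param fit a [fit_observer_model()] result.
#' @param B_perm,B_boot numbers of permutations / bootstrap resamples.
#' @param seed master seed (fanned out to the two procedures).
#' @param maxit,factr warm-refit optimizer controls.
#' @return the effect table with columns `se`, `ci_lo`, `ci_hi`, `d`,
#'   `p`, `class` added.
#' @export
infer_effects <- function(fit, B_perm = 999, B_boot = 999, seed = 1,
                          maxit = 200, factr = 1e8) {
  et <- effect_table(fit)
  perm <- permutation_null(fit, B_perm, fan_seed(seed, 1),
                           maxit = maxit, factr = factr)
  boot <- bootstrap_null(fit, B_boot, fan_seed(seed, 2),
                         maxit = maxit, factr = factr)
  n <- fit$model_data$n_participants
  obs <- et$estimate
  et$se <- apply(boot, 2, stats::sd)
  et$ci_lo <- obs - 1.96 * et$se
  et$ci_hi <- obs + 1.96 * et$se
  et$d <- vapply(seq_along(obs), function(i) {
    if (et$se[i] > 0) obs[i] / (et$se[i] * sqrt(n)) else NA_real_
  }, numeric(1))
  et$p <- vapply(seq_along(obs), function(i) {
    (1 + sum(abs(perm[, i]) >= abs(obs[i]))) / (B_perm + 1)
  }, numeric(1))
  et$class <- classify_significance(et$p)
  attr(et, "seeds") <- c(perm = fan_seed(seed, 1), boot = fan_seed(seed, 2))
  et
}
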