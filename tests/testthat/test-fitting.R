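test_that("starting values are deterministic and pairwise distinct", {
  d <- generate_dataset(group_preset("paper-like"), 3, tiny_design(2),
                        seed = 4)
  tab <- aggregate_trials(d$trials)
  s1 <- initial_values(tab, seed = 11, n_starts = 20)
  s2 <- initial_values(tab, seed = 11, n_starts = 20)
  expect_identical(s1, s2)
  dists <- as.matrix(dist(s1))
  expect_true(all(dists[upper.tri(dists)] > 0))
  s3 <- initial_values(tab, seed = 12, n_starts = 5)
  expect_false(isTRUE(all.equal(s1[2, ], s3[2, ])))
})

test_that("an all-no participant triggers the wide-default guard", {
  tr <- toy_trials()
  tr$response <- "no"
  tab <- aggregate_trials(tr)
  expect_warning(initial_values(tab, seed = 1), "all-yes or all-no")
})

test_that("the fitted optimum dominates the generating parameters and is seed-stable", {
  g <- group_preset("paper-like")
  d <- generate_dataset(g, 4, tiny_design(4), seed = 31)
  tab <- aggregate_trials(d$trials)
  fit <- fit_observer_model(tab, n_starts = 3, seed = 1)
  ll_truth <- joint_log_likelihood(g, unname(d$participants), tab)
  expect_gte(fit$loglik, ll_truth - 1e-4)
  expect_equal(fit$loglik,
               max(fit$per_start$loglik[fit$per_start$converged]))
  fit2 <- fit_observer_model(tab, n_starts = 3, seed = 1)
  expect_equal(fit2$loglik, fit$loglik, tolerance = 1e-6)
})

test_that("estimates are invariant to participant relabeling", {
  g <- group_preset("null")
  d <- generate_dataset(g, 3, design_spec(reps_per_rsa = 3,
                                          negative_rsa_retention = 1,
                                          rsa_jitter_sd = 0), seed = 17)
  tab <- aggregate_trials(d$trials)
  relab <- c(p01 = "x3", p02 = "x1", p03 = "x2")
  tab2 <- tab
  tab2$participant_id <- unname(relab[tab$participant_id])
  f1 <- fit_observer_model(tab, n_starts = 2, seed = 1)
  f2 <- fit_observer_model(tab2, n_starts = 2, seed = 1)
  expect_lt(abs(f1$loglik - f2$loglik), 0.1)
  expect_lt(abs(f1$group$tau_bar[1] - f2$group$tau_bar[1]), 0.5)
  expect_lt(abs(f1$participants[["p01"]]$tau_bar -
                  f2$participants[["x3"]]$tau_bar), 0.5)
})

test_that("doubling every cell's counts preserves estimates and doubles the data likelihood", {
  g <- group_preset("paper-like")
  d <- generate_dataset(g, 3, tiny_design(4), seed = 23)
  tab <- aggregate_trials(d$trials)
  tab2 <- tab
  tab2$n_trials <- 2L * tab$n_trials
  tab2$n_yes <- 2L * tab$n_yes
  f1 <- fit_observer_model(tab, n_starts = 2, seed = 1)
  f2 <- fit_observer_model(tab2, n_starts = 2, seed = 1)
  t1 <- vapply(f1$participants, function(p) p$tau_bar, numeric(1))
  t2 <- vapply(f2$participants, function(p) p$tau_bar, numeric(1))
  # the group penalty is fixed while the data weight doubles, so
  # estimates agree up to the (small) change in shrinkage
  expect_equal(unname(t1), unname(t2), tolerance = 0.05)
  # binomial kernel (without the count-dependent lchoose constant)
  kernel <- function(fit, tab) {
    sum(vapply(seq_along(fit$participants), function(i) {
      cells <- tab[tab$participant_id == names(fit$participants)[i], ]
      pr <- recalibr:::predicted_probabilities(fit$participants[[i]], cells)
      sum(cells$n_yes * log(pr) + (cells$n_trials - cells$n_yes) *
            log1p(-pr))
    }, numeric(1)))
  }
  expect_equal(kernel(f2, tab2) / kernel(f1, tab), 2, tolerance = 0.02)
})

test_that("a participant with a single RSA has flank parameters held at group means", {
  g <- group_preset("paper-like")
  d <- generate_dataset(g, 3, tiny_design(3), seed = 29)
  extra <- tibble::tibble(participant_id = "p99",
                          task = rep(c("simultaneity", "agency"), each = 8),
                          modality = rep(rep(c("visual", "auditory"), each = 4), 2),
                          lag = rep(rep(c("lag0", "lag150"), each = 2), 4),
                          rsa_ms = 100,
                          response = rep(c("yes", "no"), 8))
  tab <- aggregate_trials(dplyr::bind_rows(d$trials, extra))
  expect_warning(fit <- fit_observer_model(tab, n_starts = 1, seed = 1),
                 "flank")
  p99 <- fit$participants[["p99"]]
  expect_equal(log(p99$delta_bar), fit$group$delta_bar[1], tolerance = 1e-8)
  expect_equal(log(p99$sigmaL_bar), fit$group$sigmaL_bar[1], tolerance = 1e-8)
  expect_equal(unname(p99$beta_delta), unname(fit$group$beta_delta[, 1]),
               tolerance = 1e-8)
})

test_that("individual estimates shrink together when participants are identical", {
  g0 <- group_params(tau_bar = c(150, 0), delta_bar = c(log(300), 0),
                     sigmaL_bar = c(log(70), 0), m_bar = c(0, 0),
                     lapse = 0.02)
  d <- generate_dataset(g0, 4, design_spec(reps_per_rsa = 4,
                                           negative_rsa_retention = 1,
                                           rsa_jitter_sd = 0), seed = 41)
  tab <- aggregate_trials(d$trials)
  fit <- fit_observer_model(tab, n_starts = 3, seed = 1)
  taus <- vapply(fit$participants, function(p) p$tau_bar, numeric(1))
  expect_lt(max(taus) - min(taus), 25)
  expect_lt(abs(mean(taus) - 150), 15)
})

test_that("the stability check reports log-likelihood and effect spreads", {
  d <- generate_dataset(group_preset("paper-like"), 2, tiny_design(3),
                        seed = 37)
  tab <- aggregate_trials(d$trials)
  fit <- fit_observer_model(tab, n_starts = 2, seed = 1)
  sc <- stability_check(fit, n_starts_validation = 4, seed = 2)
  expect_length(sc$loglik, 4)
  expect_gte(sc$loglik_spread, 0)
  expect_equal(sc$loglik_spread, max(sc$loglik) - min(sc$loglik))
  expect_equal(nrow(sc$effect_spread), 5)  # overall + 4 cells
  expect_true(all(sc$effect_spread$spread_ms >= 0))
  expect_gte(max(sc$loglik), fit$loglik - 5)
})

test_that("effect table marginal adaptation equals the mean of the four simple effects", {
  d <- generate_dataset(group_preset("paper-like"), 3, tiny_design(3),
                        seed = 43)
  tab <- aggregate_trials(d$trials)
  fit <- fit_observer_model(tab, n_starts = 1, seed = 1)
  et <- effect_table(fit)
  for (par in c("tau", "delta")) {
    marg <- et$estimate[et$parameter == par & et$effect == "adaptation" &
                          is.na(et$cell)]
    cells <- et$estimate[et$parameter == par & et$effect == "adaptation" &
                           !is.na(et$cell)]
    expect_length(cells, 4)
    expect_equal(marg, mean(cells), tolerance = 1e-10)
  }
  # for the additive midpoint the marginal effects equal the mean
  # fitted coefficients exactly
  b_adapt <- mean(vapply(fit$participants,
                         function(p) p$beta_tau[["adaptation"]], numeric(1)))
  expect_equal(et$estimate[et$parameter == "tau" & et$effect == "adaptation" &
                             is.na(et$cell)],
               b_adapt, tolerance = 1e-8)
})
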