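test_that("effects coding follows the fixed sign convention and is balanced", {
  expect_equal(effects_code("simultaneity", "visual", "lag0"),
               c(t = -0.5, s = -0.5, a = -0.5))
  expect_equal(effects_code("agency", "auditory", "lag150"),
               c(t = 0.5, s = 0.5, a = 0.5))
  expect_error(effects_code("sj", "visual", "lag0"), "sj")
  grid <- recalibr:::condition_grid()
  codes <- t(mapply(effects_code, grid$task, grid$modality, grid$lag))
  expect_equal(unname(colSums(codes)), c(0, 0, 0))
  X <- recalibr:::code_matrix()
  expect_true(all(X[, 4:6] %in% c(-0.25, 0.25)))
  expect_true(all(X[, 7] %in% c(-0.125, 0.125)))
})

test_that("condition parameters combine grand means and effects-coded predictors", {
  p0 <- participant_params(tau_bar = 150)
  for (tk in c("simultaneity", "agency")) {
    cp <- condition_params(p0, effects_code(tk, "visual", "lag0"))
    expect_equal(cp$tau, 150)          # null predictor: grand mean everywhere
    expect_equal(cp$delta, 311)
  }
  p1 <- participant_params(tau_bar = 150,
                           beta_tau = c(0, 0, 34, 0, 0, 0, 0))
  hi <- condition_params(p1, effects_code("agency", "visual", "lag150"))
  lo <- condition_params(p1, effects_code("agency", "visual", "lag0"))
  expect_equal(hi$tau, 167)
  expect_equal(lo$tau, 133)
  expect_equal(hi$tau - lo$tau, 34)
  p2 <- participant_params(delta_bar = 311,
                           beta_delta = c(0, 0, 0.2, 0, 0, 0, 0))
  d_hi <- condition_params(p2, effects_code("simultaneity", "visual", "lag150"))
  d_lo <- condition_params(p2, effects_code("simultaneity", "visual", "lag0"))
  expect_equal(d_hi$delta, 311 * exp(0.1), tolerance = 1e-12)
  expect_equal(d_lo$delta, 311 * exp(-0.1), tolerance = 1e-12)
})

test_that("detection probability matches the two-CDF form and stays in [0, 1]", {
  cp <- list(tau = 0, delta = 2, sigmaL = 1, m = 0)
  expect_equal(detection_probability(0, cp), pnorm(1) - pnorm(-1),
               tolerance = 1e-12)
  expect_equal(detection_probability(0, cp), 0.6826895, tolerance = 1e-6)
  # degenerate window
  expect_equal(detection_probability(c(-1, 0, 1),
                                     list(tau = 0, delta = 1e-12,
                                          sigmaL = 1, m = 0)),
               rep(0, 3), tolerance = 1e-9)
  # saturation in the tails
  expect_equal(detection_probability(c(-1e5, 1e5),
                                     list(tau = 50, delta = 300,
                                          sigmaL = 60, m = 0.4)),
               c(0, 0))
  # asymmetric flanks never dip below zero after flooring
  set.seed(4)
  for (i in 1:20) {
    cp <- list(tau = runif(1, -100, 300), delta = runif(1, 50, 500),
               sigmaL = runif(1, 20, 150), m = runif(1, -1, 1))
    pr <- detection_probability(seq(-2000, 2000, by = 50), cp)
    expect_true(all(pr >= 0 & pr <= 1))
  }
})

test_that("detection probability integrates to the criterion separation in the box limit", {
  cp <- list(tau = 100, delta = 400, sigmaL = 5, m = 0)
  int <- integrate(function(x) detection_probability(x, cp),
                   -2000, 2000, subdivisions = 2000L)$value
  expect_lt(abs(int - cp$delta) / cp$delta, 0.01)
})

test_that("lapse mixing is affine with the expected fixed points and symmetry", {
  expect_equal(response_probability(0.37, 0), 0.37)
  expect_equal(response_probability(c(0, 0.3, 1), 0.5), rep(0.5, 3))
  expect_equal(response_probability(0.9, 0.02), 0.884)
  p <- seq(0, 1, by = 0.1)
  for (l in c(0.01, 0.1, 0.3)) {
    expect_equal(response_probability(1 - p, l),
                 1 - response_probability(p, l), tolerance = 1e-12)
    r <- response_probability(p, l)
    expect_true(all(r >= l - 1e-12 & r <= 1 - l + 1e-12))
  }
})

test_that("lapse-mixed probability matches a Monte-Carlo Bernoulli frequency", {
  set.seed(7)
  cp <- list(tau = 120, delta = 300, sigmaL = 70, m = 0.2)
  lapse <- 0.03
  rsa <- 60
  pr <- response_probability(detection_probability(rsa, cp), lapse)
  draws <- stats::rbinom(1, 2e5, pr) / 2e5
  expect_lt(abs(draws - pr), 0.004)
})

test_that("participant log-likelihood is the binomial log-pmf summed over cells", {
  p <- participant_params(tau_bar = 0, delta_bar = 1e-9, sigmaL_bar = 1,
                          lapse = 0.499999999)
  # lapse ~ 0.5 forces predicted probability 1/2 regardless of the curve
  cells <- tibble::tibble(task = "agency", modality = "visual",
                          lag = "lag0", rsa_ms = 0,
                          n_trials = 10L, n_yes = 5L)
  expect_equal(participant_loglik(p, cells),
               lchoose(10, 5) + 10 * log(0.5), tolerance = 1e-6)
  expect_equal(participant_loglik(p, cells), -1.402, tolerance = 1e-3)
  # additivity: a duplicated cell doubles its contribution
  expect_equal(participant_loglik(p, dplyr::bind_rows(cells, cells)),
               2 * participant_loglik(p, cells), tolerance = 1e-9)
})

test_that("certain outcomes give zero log-likelihood and contradictions give -Inf", {
  p <- participant_params(tau_bar = 0, delta_bar = 600, sigmaL_bar = 1e-6,
                          lapse = 0)
  inside <- tibble::tibble(task = "agency", modality = "visual",
                           lag = "lag0", rsa_ms = 0,
                           n_trials = 8L, n_yes = 8L)
  expect_equal(participant_loglik(p, inside), 0, tolerance = 1e-9)
  outside <- tibble::tibble(task = "agency", modality = "visual",
                            lag = "lag0", rsa_ms = 5000,
                            n_trials = 8L, n_yes = 3L)
  expect_equal(suppressMessages(participant_loglik(p, outside)), -Inf)
})

test_that("parameter counts follow the 33-per-participant plus 65 structure", {
  expect_equal(count_parameters(48),
               list(individual_total = 1584, group_total = 65,
                    grand_total = 1649))
  expect_equal(count_parameters(1)$grand_total, 98)
  for (n in c(2, 7, 30)) {
    ct <- count_parameters(n)
    expect_equal((ct$grand_total - ct$group_total) %% 33, 0)
  }
  expect_error(count_parameters(0), ">= 1")
})

test_that("the joint objective adds group log-densities to the data likelihood", {
  d <- generate_dataset(group_preset("paper-like"), n_participants = 1,
                        design = tiny_design(2), seed = 21)
  tab <- aggregate_trials(d$trials)
  g <- group_params()
  # participant sitting exactly at the group means/medians
  p_mode <- participant_params(tau_bar = g$tau_bar[1],
                               delta_bar = exp(g$delta_bar[1]),
                               sigmaL_bar = exp(g$sigmaL_bar[1]),
                               m_bar = g$m_bar[1], lapse = g$lapse)
  jll <- joint_log_likelihood(g, list(p_mode), tab)
  cells <- tab[, c("task", "modality", "lag", "rsa_ms", "n_trials", "n_yes")]
  data_ll <- participant_loglik(p_mode, cells)
  # expected penalty: each parameter's log group density at its mode, on
  # the model's optimization scales (ms/100 for tau-type parameters)
  sds <- c(g$tau_bar[2] / 100, g$delta_bar[2], g$sigmaL_bar[2], g$m_bar[2],
           g$beta_tau[, 2] / 100, g$beta_delta[, 2], g$beta_sigma[, 2],
           g$beta_m[, 2])
  sds <- pmax(sds, 1e-3)
  pen <- sum(dnorm(0, 0, sds, log = TRUE)) + dnorm(0, 0, 0.5, log = TRUE)
  expect_equal(jll - data_ll, pen, tolerance = 1e-6)
})

test_that("with diffuse group spreads the joint objective tracks the data likelihood", {
  d <- generate_dataset(group_preset("paper-like"), n_participants = 2,
                        design = tiny_design(2), seed = 22)
  tab <- aggregate_trials(d$trials)
  flat <- group_params(tau_bar = c(150, 1e5), delta_bar = c(log(311), 1e3),
                       sigmaL_bar = c(log(70), 1e3), m_bar = c(0, 1e3),
                       beta_tau = beta_block(sd0 = 1e5),
                       beta_delta = beta_block(sd0 = 1e3),
                       beta_sigma = beta_block(sd0 = 1e3),
                       beta_m = beta_block(sd0 = 1e3))
  pa <- participant_params(tau_bar = 140)
  pb <- participant_params(tau_bar = 260, delta_bar = 250)
  # the constant (the flat-density values) cancels in differences
  d1 <- joint_log_likelihood(flat, list(pa, pb), tab) -
    joint_log_likelihood(flat, list(pb, pa), tab)
  ids <- sort(unique(tab$participant_id))
  ca <- tab[tab$participant_id == ids[1], ]
  cb <- tab[tab$participant_id == ids[2], ]
  d2 <- (participant_loglik(pa, ca) + participant_loglik(pb, cb)) -
    (participant_loglik(pb, ca) + participant_loglik(pa, cb))
  expect_equal(d1, d2, tolerance = 1e-4)
})

test_that("the analytic gradient of the joint objective matches finite differences", {
  d <- generate_dataset(group_preset("paper-like"), n_participants = 3,
                        design = tiny_design(2), seed = 23)
  tab <- aggregate_trials(d$trials)
  md <- recalibr:::as_model_data(tab)
  par <- initial_values(md, seed = 2, n_starts = 2)[2, ]
  gr <- recalibr:::joint_gr(par, md)
  i_check <- c(1:10, sample.int(length(par), 40))
  eps <- 1e-6
  for (i in i_check) {
    e <- replace(numeric(length(par)), i, eps)
    ng <- (recalibr:::joint_nll(par + e, md) -
             recalibr:::joint_nll(par - e, md)) / (2 * eps)
    expect_equal(gr[i], ng, tolerance = 1e-4)
  }
})
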