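#' Specify the within-subject design to simulate
#'
#' Defaults emulate the adaptation study the model targets: 15 intended
#' RSAs from -333 to 500 ms with 10 repetitions each in every
#' 2 (task) x 2 (modality) x 2 (lag) cell. Zero and positive RSAs are
#' triggered from the keypress and realized exactly; negative RSAs rely
#' on predicting the keypress from the recent pressing rhythm, so their
#' realized values get Gaussian jitter (sd `rsa_jitter_sd`), are binned
#' to the display frame grid, and survive into the analysis only with
#' probability `negative_rsa_retention` (median retention 27% in the
#' emulated study).
#'
#' @param rsa_grid intended asynchronies in ms.
#' @param reps_per_rsa repetitions of each RSA per design cell.
#' @param negative_rsa_retention retention probability for
#'   stimulus-leading trials.
#' @param frame_ms display frame duration (120 Hz grid by default).
#' @param rsa_jitter_sd keypress-prediction error sd in ms.
#' @return list of class `design_spec`.
#' @export
design_spec <- function(rsa_grid = c(-333, -250, -133, -100, -66, -33, 0,
                                     33, 66, 100, 133, 250, 333, 417, 500),
                        reps_per_rsa = 10,
                        negative_rsa_retention = 0.27,
                        frame_ms = 1000 / 120,
                        rsa_jitter_sd = 25) {
  rsa_grid <- sort(unique(as.numeric(rsa_grid)))
  stopifnot(reps_per_rsa >= 1, negative_rsa_retention >= 0,
            negative_rsa_retention <= 1, frame_ms > 0, rsa_jitter_sd >= 0)
  structure(list(rsa_grid = rsa_grid, reps_per_rsa = as.integer(reps_per_rsa),
                 negative_rsa_retention = negative_rsa_retention,
                 frame_ms = frame_ms, rsa_jitter_sd = rsa_jitter_sd),
            class = "design_spec")
}

#' Draw one participant from the group-level distributions
#'
#' Midpoint, flank-ratio and all coefficients are Gaussian on the
#' identity scale; criterion separation and left-flank noise are
#' lognormal; the lapse is drawn on the scaled-logit scale around the
#' group lapse location (fixed sd 0.5).
#'
#' @param group a [group_params()] object.
#' @param seed RNG seed (NULL uses the global stream).
#' @return a [participant_params()] object.
#' @export
draw_participant <- function(group, seed = NULL) {
  with_seed(seed, {
    rn <- function(ms) stats::rnorm(1, ms[1], ms[2])
    rb <- function(b) stats::rnorm(7, b[, 1], b[, 2])
    participant_params(
      tau_bar = rn(group$tau_bar),
      delta_bar = exp(rn(group$delta_bar)),
      sigmaL_bar = exp(rn(group$sigmaL_bar)),
      m_bar = rn(group$m_bar),
      lapse = logit_to_lapse(stats::rnorm(1, lapse_to_logit(group$lapse),
                                          .LAPSE_SD)),
      beta_tau = rb(group$beta_tau),
      beta_delta = rb(group$beta_delta),
      beta_sigma = rb(group$beta_sigma),
      beta_m = rb(group$beta_m))
  })
}

#' Simulate one participant's trials
#'
#' For every design cell and every intended RSA x repetition:
#' non-negative RSAs are realized exactly and always kept; negative
#' RSAs are jittered, snapped to the frame grid, and kept independently
#' with the retention probability. Responses are Bernoulli draws from
#' the lapse-mixed two-criterion model at the realized asynchrony.
#'
#' @param p a [participant_params()] object.
#' @param design a [design_spec()].
#' @param seed RNG seed.
#' @param participant_id label for the output rows.
#' @return trial tibble (see [load_trials()] for the columns).
#' @export
simulate_trials <- function(p, design = design_spec(), seed = NULL,
                            participant_id = "p1") {
  grid <- condition_grid()
  rsa0 <- rep(design$rsa_grid, each = design$reps_per_rsa)
  with_seed(seed, {
    out <- vector("list", nrow(grid))
    for (ci in seq_len(nrow(grid))) {
      cd <- effects_code(grid$task[ci], grid$modality[ci], grid$lag[ci])
      cp <- condition_params(p, cd)
      rsa <- rsa0
      neg <- rsa < 0
      if (any(neg)) {
        if (design$rsa_jitter_sd > 0) {
          # imperfect keypress prediction: realized asynchrony is
          # jittered, then recorded at the display refresh
          rsa[neg] <- bin_rsa(rsa[neg] + stats::rnorm(sum(neg), 0,
                                                      design$rsa_jitter_sd),
                              design$frame_ms)
        }
        keep <- !neg
        keep[neg] <- stats::runif(sum(neg)) < design$negative_rsa_retention
      } else {
        keep <- rep(TRUE, length(rsa))
      }
      rsa <- rsa[keep]
      pr <- response_probability(detection_probability(rsa, cp), p$lapse)
      yes <- stats::rbinom(length(rsa), 1, pr)
      out[[ci]] <- tibble::tibble(participant_id = participant_id,
                                  task = grid$task[ci],
                                  modality = grid$modality[ci],
                                  lag = grid$lag[ci],
                                  rsa_ms = rsa,
                                  response = ifelse(yes == 1, "yes", "no"))
    }
    dplyr::bind_rows(out)
  })
}

#' Generate a full synthetic dataset with ground truth
#'
#' Draws `n_participants` from the group-level distributions and
#' simulates each one's trials under the design, returning the trials
#' together with the generating parameters for recovery scoring.
#'
#' @param group generating [group_params()] (see [group_preset()]).
#' @param n_participants number of participants.
#' @param design a [design_spec()].
#' @param seed master seed (fanned out per participant; a fixed seed
#'   reproduces the dataset exactly).
#' @param csv_path optional path: when given, trials are also written
#'   as the canonical CSV.
#' @return list with `trials` (tibble), `participants` (generating
#'   [participant_params()] per participant) and `group`.
#' @export
generate_dataset <- function(group = group_preset("paper-like"),
                             n_participants = 48,
                             design = design_spec(), seed = 1,
                             csv_path = NULL) {
  stopifnot(n_participants >= 1)
  ids <- sprintf("p%02d", seq_len(n_participants))
  participants <- vector("list", n_participants)
  trials <- vector("list", n_participants)
  for (i in seq_len(n_participants)) {
    participants[[i]] <- draw_participant(group, seed = fan_seed(seed, 2L * i))
    trials[[i]] <- simulate_trials(participants[[i]], design,
                                   seed = fan_seed(seed, 2L * i + 1L),
                                   participant_id = ids[i])
  }
  names(participants) <- ids
  out <- list(trials = dplyr::bind_rows(trials),
              participants = participants, group = group)
  if (!is.null(csv_path)) write_trials(out$trials, csv_path)
  out
}
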