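# Contrast weights over the 8 design cells for each effects-coded
# predictor: every marginal effect is the mean of cell values at the
# +0.5 level(s) minus the -0.5 level(s); interactions are
# differences-of-differences.  For a code column x this is w = 1/(8 x)
# elementwise (balanced design).
effect_weights <- function() {
  X <- code_matrix()
  W <- 1 / (8 * X)
  colnames(W) <- colnames(X)
  W
}

# Effect table computed directly from an internal parameter vector.
effect_table_from_par <- function(par, md) {
  sp <- split_par(par, md$n_participants)
  V <- recon_V(sp, md$flank_fixed)
  cm <- condition_matrices(V, md$X)
  W <- effect_weights()
  grid <- md$grid
  lag_hi <- grid$lag == .LAGS[2]

  rows <- list()
  per_part <- list()
  for (param in c("tau", "delta")) {
    M <- if (param == "tau") cm$Tau else cm$Del   # n_participants x 8
    # marginal effects and interactions
    eff <- M %*% W                                 # n_participants x 7
    for (j in seq_along(.EFFECT_NAMES)) {
      key <- paste(param, .EFFECT_NAMES[j], "overall")
      rows[[key]] <- tibble::tibble(parameter = param,
                                    effect = .EFFECT_NAMES[j],
                                    cell = NA_character_,
                                    estimate = mean(eff[, j]))
      per_part[[key]] <- eff[, j]
    }
    # simple adaptation effects per task x modality cell
    for (tk in .TASKS) {
      for (mo in .MODALITIES) {
        i1 <- which(grid$task == tk & grid$modality == mo & lag_hi)
        i0 <- which(grid$task == tk & grid$modality == mo & !lag_hi)
        d <- M[, i1] - M[, i0]
        key <- paste(param, "adaptation", tk, mo)
        rows[[key]] <- tibble::tibble(parameter = param,
                                      effect = "adaptation",
                                      cell = paste(tk, mo, sep = ":"),
                                      estimate = mean(d))
        per_part[[key]] <- d
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "per_participant") <- do.call(cbind, per_part)
  out
}

#' Fitted condition-effect table
#'
#' Summarizes a fit as the effects the design was built to measure: for
#' the psychometric midpoint (`tau`) and criterion separation (`delta`),
#' the marginal main effects of task, modality and adaptation, all
#' interactions (as differences-of-differences), and the simple
#' adaptation effect (lag150 minus lag0, in ms) within each of the four
#' task x modality cells. Each participant's cell values are computed
#' from their fitted parameters; group estimates are means across
#' participants. In this balanced design the marginal adaptation effect
#' equals the mean of the four simple effects exactly.
#'
#' @param fit a [fit_observer_model()] result.
#' @return tibble with columns `parameter` (`"tau"`/`"delta"`),
#'   `effect`, `cell` (`NA` for marginal rows), `estimate` (ms); the
#'   per-participant effect matrix is attached as attribute
#'   `"per_participant"`.
#' @export
effect_table <- function(fit) {
  stopifnot(inherits(fit, "recal_fit"))
  effect_table_from_par(fit$par, fit$model_data)
}

# Select one statistic (scalar group effect) from an effect table.
statistic_value <- function(et, parameter, effect, cell = NA_character_) {
  i <- which(et$parameter == parameter & et$effect == effect &
               (is.na(cell) & is.na(et$cell) |
                  (!is.na(cell) & !is.na(et$cell) & et$cell == cell)))
  if (length(i) != 1) {
    stop(sprintf("statistic not found: %s / %s / %s", parameter, effect,
                 ifelse(is.na(cell), "overall", cell)), call. = FALSE)
  }
  et$estimate[i]
}
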