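#' Read trial-level behavioural data from CSV
#'
#' Canonical long format: one row per test trial with columns
#' `participant_id`, `task`, `modality`, `lag`, `rsa_ms`, `response`.
#' Factor levels are matched case-insensitively against a configurable
#' synonym map; the RSA is the realized response-stimulus asynchrony in
#' ms (negative when the stimulus led the keypress). Rows with
#' unrecognized levels or unparseable values are collected with their
#' line numbers and reported; the load only aborts when the rejected
#' fraction exceeds `max_reject_frac`.
#'
#' @param path CSV file with a header row.
#' @param level_map named list of character vectors mapping accepted
#'   (lowercased) input strings to canonical levels; see default.
#' @param max_reject_frac abort when more than this fraction of data
#'   rows is rejected (default 0.5).
#' @return tibble of valid trials (class `recal_trials`), with
#'   attributes `n_read`, `rejected` (tibble of line, reason).
#' @export
load_trials <- function(path, level_map = default_level_map(),
                        max_reject_frac = 0.5) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  required <- c("participant_id", "task", "modality", "lag",
                "rsa_ms", "response")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  n <- nrow(raw)
  match_level <- function(x, key) {
    map <- level_map[[key]]
    out <- rep(NA_character_, length(x))
    lx <- tolower(trimws(x))
    for (canon in names(map)) out[lx %in% map[[canon]]] <- canon
    out
  }
  task <- match_level(raw$task, "task")
  modality <- match_level(raw$modality, "modality")
  lag <- match_level(raw$lag, "lag")
  response <- match_level(raw$response, "response")
  rsa <- suppressWarnings(as.numeric(raw$rsa_ms))

  reason <- rep(NA_character_, n)
  flag <- function(bad, why) {
    reason[bad & is.na(reason)] <<- why
  }
  flag(is.na(task), "unrecognized task level")
  flag(is.na(modality), "unrecognized modality level")
  flag(is.na(lag), "unrecognized lag level")
  flag(is.na(response), "unrecognized response")
  flag(is.na(rsa), "unparseable rsa_ms")

  bad <- !is.na(reason)
  rejected <- tibble::tibble(line = which(bad) + 1L,  # +1 for header row
                             reason = reason[bad])
  if (n > 0 && sum(bad) / n > max_reject_frac) {
    stop(sprintf("%d of %d rows rejected (> %.0f%%); first problem: line %d (%s)",
                 sum(bad), n, 100 * max_reject_frac,
                 rejected$line[1], rejected$reason[1]), call. = FALSE)
  }
  out <- tibble::tibble(participant_id = raw$participant_id[!bad],
                        task = task[!bad], modality = modality[!bad],
                        lag = lag[!bad], rsa_ms = rsa[!bad],
                        response = response[!bad])
  message(sprintf("load_trials: %d rows read, %d kept, %d rejected",
                  n, nrow(out), sum(bad)))
  structure(out, n_read = n, rejected = rejected,
            class = c("recal_trials", class(out)))
}

#' @rdname load_trials
#' @export
default_level_map <- function() {
  list(task = list(simultaneity = c("simultaneity", "sj", "synchrony",
                                    "simultaneity judgement"),
                   agency = c("agency", "soa", "agency judgement")),
       modality = list(visual = c("visual", "v", "vis"),
                       auditory = c("auditory", "a", "aud", "audio")),
       lag = list(lag0 = c("lag0", "0", "baseline", "lag_0"),
                  lag150 = c("lag150", "150", "adapted", "lag_150")),
       response = list(yes = c("yes", "y", "1", "true"),
                       no = c("no", "n", "0", "false")))
}

#' Write trials to the canonical CSV format
#'
#' @param trials a trial tibble (see [load_trials()]).
#' @param path output file.
#' @export
write_trials <- function(trials, path) {
  readr::write_csv(as.data.frame(trials)[, c("participant_id", "task",
                                             "modality", "lag", "rsa_ms",
                                             "response")], path)
  invisible(path)
}

# Snap asynchronies to the nearest display-frame multiple.
bin_rsa <- function(rsa, frame_ms) {
  round(rsa / frame_ms) * frame_ms
}

#' Aggregate trials into a binomial table
#'
#' Counts trials and yes-responses per participant x condition x RSA —
#' the data unit of the observer model. Stimulus-leading (negative RSA)
#' asynchronies are realized keypress times and are snapped to the
#' nearest display frame before grouping, mirroring how such trials are
#' recorded at the screen refresh; pass `rsa_binning = "exact"` for
#' pre-binned data, or `"all"` to snap every RSA.
#'
#' @param trials trial tibble.
#' @param rsa_binning `"negative"` (default), `"all"` or `"exact"`.
#' @param frame_ms frame duration of the binning grid (default
#'   1000/120, a 120 Hz display).
#' @return tibble with columns `participant_id`, `task`, `modality`,
#'   `lag`, `rsa_ms`, `n_trials`, `n_yes` (class `recal_bin_table`).
#' @export
aggregate_trials <- function(trials, rsa_binning = c("negative", "all", "exact"),
                             frame_ms = 1000 / 120) {
  rsa_binning <- match.arg(rsa_binning)
  if (nrow(trials) == 0) stop("empty trial collection", call. = FALSE)
  rsa <- trials$rsa_ms
  if (rsa_binning == "all") {
    rsa <- bin_rsa(rsa, frame_ms)
  } else if (rsa_binning == "negative") {
    neg <- rsa < 0
    rsa[neg] <- bin_rsa(rsa[neg], frame_ms)
  }
  df <- tibble::tibble(participant_id = trials$participant_id,
                       task = trials$task, modality = trials$modality,
                       lag = trials$lag, rsa_ms = rsa,
                       yes = as.integer(trials$response == "yes"))
  out <- dplyr::summarise(
    dplyr::group_by(df, .data$participant_id, .data$task, .data$modality,
                    .data$lag, .data$rsa_ms),
    n_trials = dplyr::n(), n_yes = sum(.data$yes), .groups = "drop")
  out <- dplyr::arrange(out, .data$participant_id, .data$task,
                        .data$modality, .data$lag, .data$rsa_ms)
  structure(out, class = c("recal_bin_table", class(out)))
}

#' Write an aggregated binomial table to CSV
#'
#' @param table binomial table from [aggregate_trials()].
#' @param path output file.
#' @export
write_binomial_table <- function(table, path) {
  readr::write_csv(as.data.frame(table), path)
  invisible(path)
}

#' Read an aggregated binomial table from CSV
#'
#' @param path CSV written by [write_binomial_table()].
#' @return binomial-table tibble.
#' @export
read_binomial_table <- function(path) {
  out <- readr::read_csv(path, col_types = readr::cols(
    participant_id = "c", task = "c", modality = "c", lag = "c",
    rsa_ms = "d", n_trials = "i", n_yes = "i"), progress = FALSE)
  stopifnot(all(out$n_yes >= 0), all(out$n_yes <= out$n_trials))
  structure(out, class = c("recal_bin_table", class(out)))
}

#' Exclude participant-task data with too few yes responses
#'
#' A participant whose fraction of yes responses within one task falls
#' below `min_yes_frac` has that task's trials removed (the judgement is
#' then likely driven by a non-temporal cue or belief); the other task
#' is kept. Default threshold 0.02.
#'
#' @param trials trial tibble.
#' @param min_yes_frac minimum fraction of yes responses per
#'   participant x task, in \[0, 1\].
#' @return list with `trials` (kept rows) and `report` (tibble of
#'   participant, task, yes fraction, dropped flag).
#' @export
exclusion_filter <- function(trials, min_yes_frac = 0.02) {
  if (!is.numeric(min_yes_frac) || min_yes_frac < 0 || min_yes_frac > 1) {
    stop("`min_yes_frac` must lie in [0, 1]", call. = FALSE)
  }
  report <- dplyr::summarise(
    dplyr::group_by(trials, .data$participant_id, .data$task),
    n_trials = dplyr::n(),
    yes_frac = mean(.data$response == "yes"), .groups = "drop")
  report$dropped <- report$yes_frac < min_yes_frac
  drop_keys <- paste(report$participant_id[report$dropped],
                     report$task[report$dropped])
  keep <- !(paste(trials$participant_id, trials$task) %in% drop_keys)
  list(trials = trials[keep, , drop = FALSE], report = report)
}
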