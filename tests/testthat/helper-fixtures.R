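# Small designs used across tests (kept light so the default run stays
# fast; the full design is exercised by the synthetic-data tests).
tiny_design <- function(reps = 4) {
  design_spec(rsa_grid = c(-133, -66, 0, 33, 66, 100, 133, 250, 417),
              reps_per_rsa = reps, negative_rsa_retention = 1,
              rsa_jitter_sd = 0)
}

calib_design <- function(reps = 3) {
  design_spec(rsa_grid = c(-133, -66, 0, 66, 133, 250, 417),
              reps_per_rsa = reps, negative_rsa_retention = 1,
              rsa_jitter_sd = 0)
}

# A deterministic hand-built trial tibble.
toy_trials <- function() {
  tibble::tibble(
    participant_id = rep("p1", 6),
    task = rep(c("simultaneity", "agency"), each = 3),
    modality = "visual",
    lag = "lag0",
    rsa_ms = rep(c(0, 100, 250), 2),
    response = c("yes", "yes", "no", "no", "yes", "no"))
}

expect_close <- function(object, expected, tol) {
  expect_true(abs(object - expected) <= tol,
              label = sprintf("|%g - %g| <= %g", object, expected, tol))
}
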