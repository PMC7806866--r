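#' Generate a synthetic flow-cytometry time course
#'
#' Simulates the model (optionally under a perturbation schedule, from the
#' steady DNA distribution), samples the phase percentages at the requested
#' times, and adds independent per-phase Gaussian noise truncated at zero,
#' renormalising each sample to 100%. This emulates the measurement-error
#' structure of the packaged experimental tables: by default the noise
#' standard deviations are the root-mean-square sham standard errors of the
#' reference dataset, on the percent scale. One integer seed governs the
#' whole stream, so identical calls give bit-identical tables.
#'
#' @param rates Baseline [rate_params()].
#' @param sample_times Times (h) at which to sample (default
#'   `c(0, 6, 16, 24, 48, 72)`).
#' @param schedule Optional [perturbation_schedule()]; when supplied the
#'   population is first brought to its SDD and irradiation happens at
#'   `t = 0` (so `dose_gy` in the output is taken from the schedule label
#'   when parseable).
#' @param noise_sd Per-phase additive noise SD on the percent scale, in the
#'   order G1, S, G2, M. Default `c(1.59, 1.52, 1.01, 0.28)`.
#' @param n_replicates Number of replicate tables to emit (default 1).
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @param config A [sim_config()].
#' @return A long-format experiment table
#'   (`time_h, dose_gy, phase, percent, sem, replicate`) with `provenance`
#'   attribute `"synthetic"`. The `sem` column carries the generating
#'   `noise_sd` so the table can feed [fit_unperturbed()] directly.
#' @export
generate_synthetic_timecourse <- function(rates,
                                          sample_times = c(0, 6, 16, 24, 48, 72),
                                          schedule = NULL,
                                          noise_sd = c(1.59, 1.52, 1.01, 0.28),
                                          n_replicates = 1, seed = NULL,
                                          config = sim_config()) {
  stopifnot(is_rate_params(rates))
  if (length(noise_sd) == 1) noise_sd <- rep(noise_sd, 4)
  if (length(noise_sd) != 4 || any(noise_sd < 0)) {
    abort("`noise_sd` must be 4 non-negative percent-scale SDs (G1, S, G2, M)")
  }
  if (!is.null(seed)) set.seed(seed)
  if (is.null(schedule)) {
    sdd <- evolve_to_sdd(rates, config)
    start <- sdd$state
    start$t <- 0
    tc <- simulate_timecourse(rates, horizon = max(sample_times), config = config,
                              initial = start)
    dose <- 0
  } else {
    tc <- simulate_perturbed(rates, schedule, horizon = max(sample_times),
                             config = config)
    dose <- suppressWarnings(as.numeric(sub("^([0-9.]+).*", "\\1",
                                            schedule$dose_label)))
    if (is.na(dose)) dose <- NA_real_
  }
  idx <- vapply(sample_times, function(t) which.min(abs(tc$time_h - t)), integer(1))
  clean <- 100 * as.matrix(tc[idx, FRAC_COLS])
  phases <- c("G1", "S", "G2", "M")
  rows <- list()
  for (r in seq_len(n_replicates)) {
    for (i in seq_along(sample_times)) {
      noisy <- clean[i, ] + rnorm(4, 0, noise_sd)
      noisy <- pmax(noisy, 0)
      if (sum(noisy) == 0) noisy <- clean[i, ]
      noisy <- 100 * noisy / sum(noisy)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        time_h = sample_times[i], dose_gy = dose, phase = phases,
        percent = as.numeric(noisy), sem = noise_sd, replicate = r)
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "provenance") <- "synthetic"
  out
}

#' Generate a synthetic growth curve
#'
#' Exponentially growing cell counts with multiplicative Gaussian noise:
#' `count = n0 * exp(gamma * t) * (1 + eps)`, `eps ~ N(0, cv)`.
#'
#' @param n0 Initial cell count.
#' @param gamma Growth rate (1/h).
#' @param times Sampling times (h), default `c(6, 16, 24, 48, 72)`.
#' @param cv Relative noise SD (default 0.1); 0 gives the exact exponential.
#' @param n_replicates Replicates per time point (default 1).
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @return A tibble `time_h, count, replicate` with `provenance`
#'   `"synthetic"`. Counts are floored at a small positive value so a
#'   downstream log-scale fit cannot fail.
#' @export
generate_synthetic_growth <- function(n0, gamma, times = c(6, 16, 24, 48, 72),
                                      cv = 0.1, n_replicates = 1, seed = NULL) {
  if (n0 <= 0) abort("`n0` must be > 0")
  if (cv < 0) abort("`cv` must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  grid <- tidyr::expand_grid(replicate = seq_len(n_replicates), time_h = times)
  mu <- n0 * exp(gamma * grid$time_h)
  eps <- if (cv > 0) rnorm(nrow(grid), 0, cv) else 0
  out <- tibble::tibble(time_h = grid$time_h,
                        count = pmax(mu * (1 + eps), 1e-6 * n0),
                        replicate = grid$replicate)
  attr(out, "provenance") <- "synthetic"
  out
}
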