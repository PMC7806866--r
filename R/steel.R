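#' Mean phase durations from Steel's formulas
#'
#' Converts steady phase fractions and the population doubling time `t_d`
#' into mean phase durations, assuming asynchronous balanced exponential
#' growth. The time in mitosis is estimated first as `T_M = t_d * f_m`, then
#'
#' \deqn{T_{G2} = T_D \log_2(f_{G2} + f_M + 1) - T_M}
#' \deqn{T_S = T_D \log_2(f_S + f_{G2} + f_M + 1) - T_{G2} - T_M}
#' \deqn{T_{G1} = T_D - T_S - T_{G2} - T_M}
#'
#' so the four durations sum to `t_d` exactly.
#'
#' @param fractions Phase fractions on the unit scale: a named numeric
#'   vector or one-row data frame with entries/columns `f_g1`, `f_s`,
#'   `f_g2`, `f_m` (values in `[0, 1]`, summing to ~1).
#' @param t_d Population doubling time in hours.
#' @return A one-row tibble with columns `t_g1`, `t_s`, `t_g2`, `t_m`, `t_d`
#'   (hours).
#' @examples
#' steel_phase_times(c(f_g1 = 0.6106, f_s = 0.3007, f_g2 = 0.0807, f_m = 0.0080), 38.4)
#' @export
steel_phase_times <- function(fractions, t_d) {
  f <- as_fraction_vector(fractions)
  if (t_d <= 0) abort("`t_d` must be > 0")
  t_m <- t_d * f[["m"]]
  t_g2 <- t_d * log2(f[["g2"]] + f[["m"]] + 1) - t_m
  t_s <- t_d * log2(f[["s"]] + f[["g2"]] + f[["m"]] + 1) - t_g2 - t_m
  t_g1 <- t_d - t_g2 - t_m - t_s
  times <- c(t_g1 = t_g1, t_s = t_s, t_g2 = t_g2, t_m = t_m)
  if (any(times < 0)) {
    bad <- names(times)[times < 0]
    abort(paste0("degenerate phase fractions: negative duration(s) ",
                 paste(bad, collapse = ", ")))
  }
  tibble::tibble(t_g1 = t_g1, t_s = t_s, t_g2 = t_g2, t_m = t_m, t_d = t_d)
}

as_fraction_vector <- function(fractions) {
  if (is.data.frame(fractions)) {
    if (nrow(fractions) != 1) abort("`fractions` data frame must have exactly one row")
    fractions <- unlist(fractions[, intersect(FRAC_COLS, names(fractions))])
  }
  nm <- names(fractions)
  if (!is.null(nm) && all(FRAC_COLS %in% nm)) {
    f <- as.numeric(fractions[FRAC_COLS])
  } else if (length(fractions) == 4) {
    f <- as.numeric(fractions)
  } else {
    abort("`fractions` must have entries f_g1, f_s, f_g2, f_m (or be length 4 in that order)")
  }
  if (any(f < 0) || any(f > 1)) {
    abort("phase fractions must lie in [0, 1] (unit scale; divide percentages by 100)")
  }
  tot <- sum(f)
  if (abs(tot - 1) > 1e-3) {
    warn(sprintf("phase fractions sum to %.4f; expected ~1 (not renormalising)", tot))
  }
  setNames(f, PHASES)
}

#' Kinetic rates from mean phase durations
#'
#' Inverts the duration-rate relations `T_G1 = 1/(k1 + mu_g1)` etc.: with
#' zero death rates each transition rate is simply the reciprocal of the
#' mean time spent in the phase.
#'
#' @param times A one-row data frame (as from [steel_phase_times()]) or a
#'   named vector with `t_g1`, `t_s`, `t_g2`, `t_m` (hours, all > 0).
#' @param mu_g1,mu_s,mu_g2,mu_m Death rates (1/h), default 0.
#' @return A [rate_params()] object.
#' @export
rates_from_phase_times <- function(times, mu_g1 = 0, mu_s = 0, mu_g2 = 0, mu_m = 0) {
  if (is.data.frame(times)) {
    if (nrow(times) != 1) abort("`times` must have exactly one row")
    times <- unlist(times)
  }
  need <- c("t_g1", "t_s", "t_g2", "t_m")
  if (!all(need %in% names(times))) abort("`times` must contain t_g1, t_s, t_g2, t_m")
  tv <- as.numeric(times[need])
  if (any(tv <= 0)) abort("all phase durations must be > 0 to take reciprocals")
  k <- 1 / tv - c(mu_g1, mu_s, mu_g2, mu_m)
  if (any(k < 0)) {
    abort(paste0("death rate exceeds 1/duration for: ",
                 paste(need[k < 0], collapse = ", ")))
  }
  rate_params(k1 = k[1], g = k[2], k2 = k[3], b = k[4],
              mu_g1 = mu_g1, mu_s = mu_s, mu_g2 = mu_g2, mu_m = mu_m)
}

#' Steel initialisation: fractions + doubling time to kinetic rates
#'
#' Convenience composition of [steel_phase_times()] and
#' [rates_from_phase_times()].
#'
#' @inheritParams steel_phase_times
#' @inheritParams rates_from_phase_times
#' @return A [rate_params()] object.
#' @examples
#' steel_rates(c(f_g1 = 0.6106, f_s = 0.3007, f_g2 = 0.0807, f_m = 0.0080), 38.4)
#' @export
steel_rates <- function(fractions, t_d, mu_g1 = 0, mu_s = 0, mu_g2 = 0, mu_m = 0) {
  rates_from_phase_times(steel_phase_times(fractions, t_d),
                         mu_g1 = mu_g1, mu_s = mu_s, mu_g2 = mu_g2, mu_m = mu_m)
}

#' Average sham phase fractions over the exponential-growth window
#'
#' Averages the phase percentages of an experiment table (long format, as
#' returned by [load_fixture()]) over the selected dose and time points.
#' Per-phase uncertainties are combined as the root-mean-square of the
#' per-time-point standard errors, matching how the reference dataset
#' reports the spread of its window average.
#'
#' @param table Long-format tibble with columns `time_h`, `dose_gy`,
#'   `phase`, `percent`, `sem`.
#' @param dose_gy Dose to select (default 0, the sham).
#' @param times Time points to average over (default `c(0, 6, 16, 24)`,
#'   the window in which unirradiated cells are still in exponential
#'   growth, before confluence).
#' @return A one-row tibble with `f_g1 ... f_m` and `sem_g1 ... sem_m`, on
#'   the unit scale.
#' @export
average_fractions <- function(table, dose_gy = 0, times = c(0, 6, 16, 24)) {
  check_experiment_table(table)
  sub <- dplyr::filter(table, .data$dose_gy == !!dose_gy, .data$time_h %in% !!times)
  if (nrow(sub) == 0) abort("no rows match the requested dose and times")
  avg <- sub |>
    dplyr::group_by(.data$phase) |>
    dplyr::summarise(f = mean(.data$percent) / 100,
                     sem = sqrt(mean(.data$sem^2)) / 100, .groups = "drop")
  wide <- tibble::tibble(
    f_g1 = avg$f[avg$phase == "G1"], f_s = avg$f[avg$phase == "S"],
    f_g2 = avg$f[avg$phase == "G2"], f_m = avg$f[avg$phase == "M"],
    sem_g1 = avg$sem[avg$phase == "G1"], sem_s = avg$sem[avg$phase == "S"],
    sem_g2 = avg$sem[avg$phase == "G2"], sem_m = avg$sem[avg$phase == "M"])
  wide
}
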