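#' Piecewise-constant perturbation schedules
#'
#' A perturbation schedule represents the effect of irradiation as
#' step-function multipliers applied to the baseline kinetic rates from the
#' moment of exposure (`t = 0`). Segments must be ordered, non-overlapping
#' and tile `[0, Inf)`; evaluation is right-continuous (a breakpoint takes
#' the value of the segment starting there).
#'
#' @param segments Data frame with columns `t_start`, `t_end` (hours post
#'   irradiation; the last `t_end` must be `Inf`) and multiplier columns
#'   `k1`, `g`, `k2`, `b` (missing columns default to 1; all > 0).
#' @param dose_label Free-text label (e.g. `"2 Gy"`).
#' @return An object of class `perturbation_schedule`.
#' @seealso [preset_schedule()] for the built-in 0/2/5 Gy presets.
#' @export
perturbation_schedule <- function(segments, dose_label = "") {
  segments <- tibble::as_tibble(segments)
  if (!all(c("t_start", "t_end") %in% names(segments))) {
    abort("`segments` needs columns t_start and t_end")
  }
  for (col in c("k1", "g", "k2", "b")) {
    if (!col %in% names(segments)) segments[[col]] <- 1
  }
  segments <- segments[c("t_start", "t_end", "k1", "g", "k2", "b")]
  segments <- dplyr::arrange(segments, .data$t_start)
  if (any(segments$t_start >= segments$t_end)) abort("each segment needs t_start < t_end")
  if (segments$t_start[1] != 0) abort("segments must start at t = 0")
  if (is.finite(segments$t_end[nrow(segments)])) abort("the last segment must extend to Inf")
  if (nrow(segments) > 1 &&
      any(abs(segments$t_start[-1] - segments$t_end[-nrow(segments)]) > 1e-9)) {
    abort("segments must tile [0, Inf) with no gaps or overlaps")
  }
  mult <- as.matrix(segments[c("k1", "g", "k2", "b")])
  if (any(mult <= 0)) abort("all multipliers must be > 0")
  structure(list(segments = segments, dose_label = dose_label),
            class = "perturbation_schedule")
}

schedule_segments <- function(schedule) schedule$segments

find_segment <- function(segments, t) {
  i <- findInterval(t, segments$t_start)
  if (i < 1L) abort("schedule evaluation before t = 0")
  i
}

apply_multipliers <- function(baseline, seg) {
  rate_params(k1 = baseline$k1 * seg$k1, g = baseline$g * seg$g,
              k2 = baseline$k2 * seg$k2, b = baseline$b * seg$b,
              mu_g1 = baseline$mu_g1, mu_s = baseline$mu_s,
              mu_g2 = baseline$mu_g2, mu_m = baseline$mu_m)
}

#' @export
print.perturbation_schedule <- function(x, ...) {
  cat(sprintf("<perturbation_schedule> %s (%d segments)\n",
              if (nzchar(x$dose_label)) x$dose_label else "unlabelled",
              nrow(x$segments)))
  print(x$segments)
  invisible(x)
}

#' Built-in radiation perturbation presets
#'
#' Step-function multiplier schedules reproducing the observed G2 block and
#' subsequent G1 accumulation after X-ray exposure of 2 or 5 Gy (times in
#' hours post irradiation):
#'
#' * **2 Gy** — `k2` divided by 12 on `[0, 6)` (G2 block), then raised to
#'   1/2 of baseline from 6 h onward; `k1` unchanged until 6 h, divided by
#'   10 on `[6, 48)`, then doubled (i.e. 1/5 of baseline) from 48 h on.
#' * **5 Gy** — `k2` divided by 12 on `[0, 24)` (the longer block; the
#'   16-24 h interval is not pinned by the data and is held at 1/12), then
#'   restored to 1/4 of baseline; `k1` unchanged until 16 h, then divided
#'   by 10 for good.
#' * **0 Gy** — identity (all multipliers 1).
#'
#' @param dose_gy One of 0, 2, 5.
#' @return A [perturbation_schedule()].
#' @examples
#' preset_schedule(2)
#' @export
preset_schedule <- function(dose_gy) {
  if (length(dose_gy) != 1 || !dose_gy %in% c(0, 2, 5)) {
    abort("`dose_gy` must be one of 0, 2, 5")
  }
  segs <- switch(as.character(dose_gy),
    "0" = tibble::tibble(t_start = 0, t_end = Inf, k1 = 1, k2 = 1),
    "2" = tibble::tibble(t_start = c(0, 6, 48), t_end = c(6, 48, Inf),
                         k1 = c(1, 1 / 10, 1 / 5), k2 = c(1 / 12, 1 / 2, 1 / 2)),
    "5" = tibble::tibble(t_start = c(0, 16, 24), t_end = c(16, 24, Inf),
                         k1 = c(1, 1 / 10, 1 / 10), k2 = c(1 / 12, 1 / 12, 1 / 4)))
  perturbation_schedule(segs, dose_label = sprintf("%g Gy", dose_gy))
}

#' Rates in force at a given time under a schedule
#'
#' Multiplies the baseline rates by the segment containing `t`
#' (right-continuous: at a breakpoint the later segment applies).
#'
#' @param schedule A [perturbation_schedule()].
#' @param baseline A [rate_params()] object.
#' @param t Time in hours post irradiation (>= 0).
#' @return A [rate_params()] object.
#' @export
rates_at <- function(schedule, baseline, t) {
  stopifnot(inherits(schedule, "perturbation_schedule"), is_rate_params(baseline))
  if (t < 0) abort("`t` must be >= 0")
  segs <- schedule_segments(schedule)
  apply_multipliers(baseline, segs[find_segment(segs, t), ])
}

#' Simulate a radiation-perturbed time course
#'
#' Brings the unperturbed population to its steady DNA distribution
#' ([evolve_to_sdd()]), then applies the perturbation schedule with the
#' irradiation instant rescaled to `t = 0` and records phase fractions up
#' to `horizon` hours. At `t = 0` the fractions equal the SDD fractions.
#'
#' @param baseline Unperturbed [rate_params()].
#' @param schedule A [perturbation_schedule()] (e.g. [preset_schedule()]).
#' @param horizon Hours post irradiation to simulate (default 72).
#' @param config A [sim_config()].
#' @return A tibble `time_h, f_g1, f_s, f_g2, f_m, n_total` (unit-scale
#'   fractions; `time_h` is hours since irradiation).
#' @examples
#' \donttest{
#' base <- rate_params(0.0429, 0.0796, 0.2347, 2.3655)
#' tc <- simulate_perturbed(base, preset_schedule(2))
#' }
#' @export
simulate_perturbed <- function(baseline, schedule, horizon = 72,
                               config = sim_config()) {
  stopifnot(is_rate_params(baseline), inherits(schedule, "perturbation_schedule"))
  sdd <- evolve_to_sdd(baseline, config)
  start <- sdd$state
  start$t <- 0
  simulate_timecourse(baseline, horizon = horizon, config = config,
                      initial = start, schedule = schedule)
}
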