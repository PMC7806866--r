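#' Relative difference between irradiated and sham percentages
#'
#' `delta = (f_dose - f_sham) / f_sham`, the fractional change of a phase
#' percentage relative to the sham control. When standard errors are given,
#' the uncertainty is propagated to first order assuming independent errors:
#' `err = |delta'| * sqrt((sem_dose/f_sham)^2 + (f_dose * sem_sham / f_sham^2)^2)`
#' evaluated elementwise.
#'
#' @param f_dose,f_sham Percentages (or fractions, consistently) for the
#'   irradiated and sham conditions; vectorised.
#' @param sem_dose,sem_sham Optional standard errors (same scale).
#' @return A tibble with columns `delta` and `err` (`err` is `NA` when no
#'   uncertainties are supplied).
#' @examples
#' relative_difference(22.47, 7.04)  # G2 phase, 6 h, 2 Gy
#' @export
relative_difference <- function(f_dose, f_sham, sem_dose = NULL, sem_sham = NULL) {
  if (any(f_sham <= 0)) abort("`f_sham` must be > 0 (relative difference undefined)")
  delta <- (f_dose - f_sham) / f_sham
  if (is.null(sem_dose) || is.null(sem_sham)) {
    err <- rep(NA_real_, length(delta))
  } else {
    err <- sqrt((sem_dose / f_sham)^2 + (f_dose * sem_sham / f_sham^2)^2)
  }
  tibble::tibble(delta = delta, err = err)
}

#' Relative-difference table from an experiment table
#'
#' Applies [relative_difference()] phase-by-phase and time-by-time to every
#' irradiated dose in a long-format experiment table, using the sham
#' (`dose_gy == 0`) rows at the same time points as the reference.
#'
#' @param table Long-format tibble with columns `time_h`, `dose_gy`,
#'   `phase`, `percent`, `sem`.
#' @return A tibble `time_h, dose_gy, phase, delta, err` covering all
#'   non-zero doses and time points with a sham counterpart.
#' @export
relative_differences <- function(table) {
  check_experiment_table(table)
  sham <- dplyr::filter(table, .data$dose_gy == 0) |>
    dplyr::select("time_h", "phase", f_sham = "percent", sem_sham = "sem")
  dosed <- dplyr::filter(table, .data$dose_gy != 0)
  if (nrow(dosed) == 0) abort("table has no irradiated rows")
  joined <- dplyr::inner_join(dosed, sham, by = c("time_h", "phase"))
  rd <- relative_difference(joined$percent, joined$f_sham,
                            joined$sem, joined$sem_sham)
  dplyr::bind_cols(dplyr::select(joined, "time_h", "dose_gy", "phase"), rd) |>
    dplyr::arrange(.data$time_h, .data$dose_gy,
                   factor(.data$phase, levels = c("G1", "S", "G2", "M")))
}
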