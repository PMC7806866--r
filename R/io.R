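#' Packaged experimental fixtures
#'
#' The reference IMR90 flow-cytometry dataset shipped with the package:
#' `"table1"` holds the measured percentages of vital cells per cell-cycle
#' phase for sham, 2 Gy and 5 Gy at 0-72 h with their standard errors;
#' `"table2"` holds the published relative differences of the irradiated
#' conditions with respect to the sham (`delta`, `err`).
#'
#' @param name `"table1"` or `"table2"`.
#' @return A tibble; `table1` has columns `time_h, dose_gy, phase, percent,
#'   sem`, `table2` has `time_h, dose_gy, phase, delta, err`. The
#'   `provenance` attribute is `"fixture"`.
#' @examples
#' load_fixture("table1")
#' @export
load_fixture <- function(name) {
  if (length(name) != 1 || !name %in% c("table1", "table2")) {
    abort("unknown fixture; available: \"table1\", \"table2\"")
  }
  path <- system.file("extdata", paste0(name, ".csv"), package = "radcycle",
                      mustWork = TRUE)
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  attr(tbl, "provenance") <- "fixture"
  tbl
}

check_experiment_table <- function(table) {
  need <- c("time_h", "dose_gy", "phase", "percent")
  if (!is.data.frame(table) || !all(need %in% names(table))) {
    abort("expected a long-format experiment table with columns time_h, dose_gy, phase, percent[, sem]")
  }
  invisible(table)
}

#' Reshape a long experiment table to wide percent columns
#'
#' @param table Long experiment table (`time_h, dose_gy, phase, percent,
#'   sem`) or an already-wide data frame with `p_*` columns (returned
#'   as-is, filtered to `times` when given).
#' @param dose_gy Dose to select.
#' @param times Optional time points to keep.
#' @return Tibble with columns `time_h`, `p_g1 ... p_m` and (when present)
#'   `sem_g1 ... sem_m`, percent scale.
#' @export
as_percent_wide <- function(table, dose_gy = 0, times = NULL) {
  if (all(paste0("p_", PHASES) %in% names(table))) {
    wide <- tibble::as_tibble(table)
    if (!is.null(times)) wide <- dplyr::filter(wide, .data$time_h %in% !!times)
    return(wide)
  }
  check_experiment_table(table)
  sub <- dplyr::filter(table, .data$dose_gy == !!dose_gy)
  if (!is.null(times)) sub <- dplyr::filter(sub, .data$time_h %in% !!times)
  if (nrow(sub) == 0) abort("no rows match the requested dose/times")
  sub$phase <- tolower(sub$phase)
  vals <- c("percent", if ("sem" %in% names(sub)) "sem")
  wide <- tidyr::pivot_wider(sub[c("time_h", "phase", vals)],
                             names_from = "phase", values_from = dplyr::all_of(vals))
  if ("sem" %in% vals) {
    names(wide) <- sub("^percent_", "p_", names(wide))
    names(wide) <- sub("^sem_", "sem_", names(wide))
  } else {
    names(wide)[-1] <- paste0("p_", names(wide)[-1])
  }
  dplyr::arrange(wide, .data$time_h)
}

#' Read / write phase-fraction time courses
#'
#' Time-course CSVs carry unit-scale fractions with a mandatory header:
#' columns `time_h`, `f_g1`, `f_s`, `f_g2`, `f_m` and optional `sem_*`
#' columns.
#'
#' @param path File path.
#' @return `read_timecourse()` returns a tibble; `write_timecourse()`
#'   returns `path` invisibly.
#' @export
read_timecourse <- function(path) {
  tbl <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("time_h", FRAC_COLS) %in% names(tbl))) {
    abort("time-course CSV must have columns time_h, f_g1, f_s, f_g2, f_m")
  }
  tbl
}

#' @rdname read_timecourse
#' @param timecourse Tibble with `time_h` and `f_*` columns.
#' @export
write_timecourse <- function(timecourse, path) {
  if (!all(c("time_h", FRAC_COLS) %in% names(timecourse))) {
    abort("`timecourse` must have columns time_h, f_g1, f_s, f_g2, f_m")
  }
  readr::write_csv(timecourse, path)
  invisible(path)
}

#' Read / write flat key-value configuration files
#'
#' Rate parameters and simulation settings are stored as a flat JSON object
#' with keys `k1, g, k2, b, mu_g1, mu_s, mu_g2, mu_m, dt, sdd_tol, sdd_lag`.
#' Unknown keys are preserved on read.
#'
#' @param path File path.
#' @return `read_rate_config()` returns a list with elements `rates`
#'   (a [rate_params()]) and `config` (a [sim_config()], using defaults for
#'   absent keys).
#' @export
read_rate_config <- function(path) {
  kv <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("k1", "g", "k2", "b")
  if (!all(need %in% names(kv))) abort("config must define k1, g, k2 and b")
  rates <- rate_params(kv$k1, kv$g, kv$k2, kv$b,
                       mu_g1 = kv$mu_g1 %||% 0, mu_s = kv$mu_s %||% 0,
                       mu_g2 = kv$mu_g2 %||% 0, mu_m = kv$mu_m %||% 0)
  defaults <- sim_config()
  config <- sim_config(dt = kv$dt %||% defaults$dt,
                       sdd_tol = kv$sdd_tol %||% defaults$sdd_tol,
                       sdd_lag = kv$sdd_lag %||% defaults$sdd_lag)
  list(rates = rates, config = config, extra = kv[setdiff(names(kv),
       c(need, "mu_g1", "mu_s", "mu_g2", "mu_m", "dt", "sdd_tol", "sdd_lag"))])
}

#' @rdname read_rate_config
#' @param rates A [rate_params()] object.
#' @param config Optional [sim_config()] whose `dt`, `sdd_tol`, `sdd_lag`
#'   are stored alongside.
#' @export
write_rate_config <- function(rates, path, config = NULL) {
  stopifnot(is_rate_params(rates))
  kv <- rates[c("k1", "g", "k2", "b", "mu_g1", "mu_s", "mu_g2", "mu_m")]
  if (!is.null(config)) {
    kv <- c(kv, config[c("dt", "sdd_tol", "sdd_lag")])
  }
  jsonlite::write_json(kv, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Read / write perturbation schedules
#'
#' Schedules are stored as a JSON list of segments, each with `t_start`,
#' `t_end` (the string `"Inf"` is accepted for the open last segment) and
#' multiplier keys `k1_factor`, `g_factor`, `k2_factor`, `b_factor`.
#'
#' @param path File path.
#' @return `read_schedule()` returns a [perturbation_schedule()].
#' @export
read_schedule <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  segs <- tibble::tibble(
    t_start = as.numeric(raw$segments$t_start),
    t_end = as.numeric(raw$segments$t_end),
    k1 = raw$segments$k1_factor %||% 1, g = raw$segments$g_factor %||% 1,
    k2 = raw$segments$k2_factor %||% 1, b = raw$segments$b_factor %||% 1)
  perturbation_schedule(segs, dose_label = raw$dose_label %||% "")
}

#' @rdname read_schedule
#' @param schedule A [perturbation_schedule()].
#' @export
write_schedule <- function(schedule, path) {
  stopifnot(inherits(schedule, "perturbation_schedule"))
  segs <- schedule_segments(schedule)
  out <- list(dose_label = schedule$dose_label,
              segments = list(t_start = segs$t_start,
                              t_end = ifelse(is.finite(segs$t_end),
                                             segs$t_end, "Inf"),
                              k1_factor = segs$k1, g_factor = segs$g,
                              k2_factor = segs$k2, b_factor = segs$b))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
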