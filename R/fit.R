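#' Chi-square objective between model and measured phase percentages
#'
#' \deqn{\Phi = \sum_k \sum_j (M_j(t_k) - f_j(t_k))^2 / \sigma_{f_j}^2(t_k)}
#' over the four phases `j` and the time points `k`, on the percent scale
#' (0-100) matching how the experimental tables are reported.
#'
#' @param model Data frame of model percentages with columns `time_h` and
#'   `p_g1`, `p_s`, `p_g2`, `p_m`; a single row is recycled over all data
#'   time points (the unperturbed model is constant at steady state).
#' @param data Data frame of measured percentages with columns `time_h`,
#'   `p_g1 ... p_m` and `sem_g1 ... sem_m` (all SEMs > 0).
#' @return The scalar objective value.
#' @examples
#' d <- tibble::tibble(time_h = 0, p_g1 = 61.06, p_s = 30.07, p_g2 = 8.07, p_m = 0.80,
#'                     sem_g1 = 1.59, sem_s = 1.52, sem_g2 = 1.01, sem_m = 0.28)
#' chi_square_objective(dplyr::mutate(d, p_g1 = 62), d)
#' @export
chi_square_objective <- function(model, data) {
  pcols <- paste0("p_", PHASES)
  scols <- paste0("sem_", PHASES)
  if (!all(c("time_h", pcols) %in% names(model))) {
    abort("`model` must have columns time_h, p_g1, p_s, p_g2, p_m")
  }
  if (!all(c("time_h", pcols, scols) %in% names(data))) {
    abort("`data` must have columns time_h, p_g1..p_m and sem_g1..sem_m")
  }
  sems <- as.matrix(data[scols])
  if (any(sems <= 0)) abort("all SEMs must be > 0 (zero uncertainty is not allowed in the chi-square)")
  if (nrow(model) == 1) {
    M <- matrix(as.numeric(model[1, pcols]), nrow(data), 4, byrow = TRUE)
  } else {
    idx <- match(data$time_h, model$time_h)
    if (anyNA(idx)) abort("`model` and `data` time grids do not match")
    M <- as.matrix(model[idx, pcols])
  }
  sum((M - as.matrix(data[pcols]))^2 / sems^2)
}

paper_fit_bounds <- function() {
  list(k1 = c(0.03, 0.06), g = c(0.05, 0.5), k2 = c(0.05, 0.5), b = c(2, 5))
}

#' Calibrate kinetic rates against unperturbed (sham) data
#'
#' Minimises the chi-square objective [chi_square_objective()] where the
#' model prediction for every candidate `(k1, g, k2, b)` is the
#' time-constant vector of steady-state (SDD) phase percentages implied by
#' those rates — computed by the closed-form dominant eigenmode
#' ([sdd_fractions()]), whose equivalence with long-run simulation is
#' property-tested.
#'
#' The optimiser is a bounded sequential (coordinate-wise) minimisation over
#' `k1`, `g`, `k2`, `b` in that order, cycled until the objective improves
#' by less than `tol` between cycles (at most `max_cycles` cycles). An
#' optional first pass holds the division rate fixed at `fix_b_at` (the
#' M-phase percentages are small and `b` is weakly identified), after which
#' all four parameters are released. Candidate minima whose implied cycle
#' length `1/k1 + 1/g + 1/k2 + 1/b` deviates from the measured doubling
#' time `t_d` by more than `cycle_length_factor` (relative) are rejected:
#' the steady-state composition constrains only rate ratios, so the
#' doubling time is the one piece of information pinning the overall scale.
#'
#' @param data Measured percentages: a long-format experiment table
#'   (columns `time_h, dose_gy, phase, percent, sem`; the `dose_gy == 0`
#'   rows at `times` are used) or an already-wide data frame with columns
#'   `time_h`, `p_g1 ... p_m`, `sem_g1 ... sem_m`.
#' @param t_d Measured population doubling time (hours), used for the Steel
#'   initialisation (when `init` is `NULL`) and the cycle-length
#'   admissibility check.
#' @param init Optional [rate_params()] initial guess; default Steel's
#'   formulas applied to the window-averaged data fractions.
#' @param bounds Named list of `c(lower, upper)` for `k1`, `g`, `k2`, `b`;
#'   defaults to the reference calibration's kept fit bounds.
#' @param times Sham time points to fit (default `c(0, 6, 16, 24)`; later
#'   sham samples approach confluence and are excluded).
#' @param fix_b_at Value at which `b` is held in the first pass (default 3);
#'   `NULL` skips that pass.
#' @param dt Time step used for the SDD fractions (default 0.05 h).
#' @param cycle_length_factor Maximum allowed relative deviation of the
#'   implied cycle length from `t_d` (default 0.25).
#' @param tol,max_cycles Sequential-minimisation stopping controls.
#' @return An object of class `unperturbed_fit`: `rates`, `objective`,
#'   `n_eval`, `implied_cycle_length`, `init`, `objective_init`, `trace`
#'   (objective per cycle), `bounds`, `data` and `admissible`.
#' @export
fit_unperturbed <- function(data, t_d, init = NULL, bounds = paper_fit_bounds(),
                            times = c(0, 6, 16, 24), fix_b_at = 3, dt = 0.05,
                            cycle_length_factor = 0.25, tol = 1e-6,
                            max_cycles = 50) {
  wide <- as_percent_wide(data, dose_gy = 0, times = times)
  if (!all(c("k1", "g", "k2", "b") %in% names(bounds))) {
    abort("`bounds` must be a named list with entries k1, g, k2, b")
  }
  if (is.null(init)) {
    favg <- average_fractions_wide(wide)
    init <- steel_rates(favg, t_d)
  }
  stopifnot(is_rate_params(init))
  par <- unlist(init[c("k1", "g", "k2", "b")])
  lo <- vapply(bounds[c("k1", "g", "k2", "b")], `[`, numeric(1), 1)
  hi <- vapply(bounds[c("k1", "g", "k2", "b")], `[`, numeric(1), 2)
  par <- pmin(pmax(par, lo), hi)
  n_eval <- 0L
  phi <- function(p) {
    n_eval <<- n_eval + 1L
    f <- sdd_mode_analytic(rate_params(p[1], p[2], p[3], p[4]), dt)$fractions
    model <- tibble::tibble(time_h = wide$time_h[1],
                            p_g1 = 100 * f[["g1"]], p_s = 100 * f[["s"]],
                            p_g2 = 100 * f[["g2"]], p_m = 100 * f[["m"]])
    chi_square_objective(model, wide)
  }
  trace <- numeric(0)
  run_passes <- function(par, fixed_b) {
    cur <- phi(par)
    for (cyc in seq_len(max_cycles)) {
      obj <- cur
      for (i in 1:4) {
        if (!is.null(fixed_b) && i == 4L) {
          par[4] <- fixed_b
          cur <- phi(par)
          next
        }
        opt <- optimize(function(x) { p <- par; p[i] <- x; phi(p) },
                        interval = c(lo[i], hi[i]), tol = 1e-8)
        if (opt$objective <= cur) {  # never let a 1-D pass increase the objective
          par[i] <- opt$minimum
          cur <- opt$objective
        }
      }
      trace <<- c(trace, cur)
      if (obj - cur < tol) break
    }
    par
  }
  obj_init <- phi(par)
  if (!is.null(fix_b_at)) par <- run_passes(par, fix_b_at)
  par <- run_passes(par, NULL)
  rates <- rate_params(par[1], par[2], par[3], par[4])
  objective <- phi(par)
  icl <- implied_cycle_length(rates)
  admissible <- abs(icl - t_d) / t_d <= cycle_length_factor
  res <- structure(list(rates = rates, objective = objective, n_eval = n_eval,
                        implied_cycle_length = icl, init = init,
                        objective_init = obj_init, trace = trace,
                        bounds = bounds, data = wide, t_d = t_d,
                        admissible = admissible, dt = dt),
                   class = "unperturbed_fit")
  if (!admissible) {
    abort(message = sprintf(
      "no admissible minimum: implied cycle length %.3g h deviates from t_d = %.3g h by more than %.0f%%",
      icl, t_d, 100 * cycle_length_factor),
      class = "radcycle_inadmissible_fit", best = res)
  }
  res
}

average_fractions_wide <- function(wide) {
  f <- colMeans(as.matrix(wide[paste0("p_", PHASES)])) / 100
  setNames(f, FRAC_COLS)
}

#' @export
print.unperturbed_fit <- function(x, ...) {
  cat("<unperturbed_fit>\n")
  cat(sprintf("  k1 = %.4f  g = %.4f  k2 = %.4f  b = %.4f (1/h)\n",
              x$rates$k1, x$rates$g, x$rates$k2, x$rates$b))
  cat(sprintf("  objective %.4g (init %.4g), %d evaluations, %d cycles\n",
              x$objective, x$objective_init, x$n_eval, length(x$trace)))
  cat(sprintf("  implied cycle length %.3g h vs measured T_D %.3g h\n",
              x$implied_cycle_length, x$t_d))
  invisible(x)
}

#' @rdname fit_unperturbed
#' @param x,object An `unperturbed_fit` object.
#' @param ... Unused.
#' @export
tidy.unperturbed_fit <- function(x, ...) {
  terms <- c("k1", "g", "k2", "b")
  tibble::tibble(
    term = terms,
    estimate = unlist(x$rates[terms]),
    init = unlist(x$init[terms]),
    lower = vapply(x$bounds[terms], `[`, numeric(1), 1),
    upper = vapply(x$bounds[terms], `[`, numeric(1), 2))
}

#' @rdname fit_unperturbed
#' @export
glance.unperturbed_fit <- function(x, ...) {
  tibble::tibble(objective = x$objective, objective_init = x$objective_init,
                 n_eval = x$n_eval, n_cycles = length(x$trace),
                 implied_cycle_length = x$implied_cycle_length,
                 t_d = x$t_d, admissible = x$admissible)
}

#' @rdname fit_unperturbed
#' @export
autoplot.unperturbed_fit <- function(object, ...) {
  f <- 100 * sdd_fractions(object$rates, object$dt)
  dat <- tidyr::pivot_longer(object$data, cols = dplyr::starts_with("p_"),
                             names_to = "phase", names_prefix = "p_",
                             values_to = "percent")
  sems <- tidyr::pivot_longer(object$data, cols = dplyr::starts_with("sem_"),
                              names_to = "phase", names_prefix = "sem_",
                              values_to = "sem")
  dat$sem <- sems$sem
  dat$phase <- factor(toupper(dat$phase), levels = c("G1", "S", "G2", "M"))
  model <- tibble::tibble(phase = factor(c("G1", "S", "G2", "M"),
                                         levels = c("G1", "S", "G2", "M")),
                          percent = as.numeric(f))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$time_h, y = .data$percent)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$percent - .data$sem,
                                          ymax = .data$percent + .data$sem)) +
    ggplot2::geom_hline(data = model, ggplot2::aes(yintercept = .data$percent),
                        colour = "steelblue", linetype = 2) +
    ggplot2::facet_wrap(~phase, scales = "free_y") +
    ggplot2::labs(x = "time (h)", y = "% of cells",
                  title = "Fitted steady-state composition vs sham data") +
    ggplot2::theme_minimal()
}
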