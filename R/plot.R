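#' Plot a phase-fraction time course
#'
#' Line plot of the four phase fractions (or percentages) versus time, with
#' optional experimental points overlaid.
#'
#' @param timecourse Tibble with `time_h` and `f_g1 ... f_m` columns (as
#'   produced by [simulate_timecourse()] or [simulate_perturbed()]).
#' @param data Optional long experiment table (`time_h, dose_gy, phase,
#'   percent, sem`) to overlay as points with error bars.
#' @param dose_gy Dose to select from `data` (default 0).
#' @param percent Plot on the percent scale (default TRUE).
#' @return A ggplot object.
#' @export
plot_timecourse <- function(timecourse, data = NULL, dose_gy = 0, percent = TRUE) {
  scale <- if (percent) 100 else 1
  long <- tidyr::pivot_longer(timecourse[c("time_h", FRAC_COLS)],
                              cols = dplyr::all_of(FRAC_COLS),
                              names_to = "phase", names_prefix = "f_",
                              values_to = "fraction")
  long$phase <- factor(toupper(long$phase), levels = c("G1", "S", "G2", "M"))
  long$value <- long$fraction * scale
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$time_h, y = .data$value,
                                          colour = .data$phase)) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "time (h)", y = if (percent) "% of cells" else "fraction of cells",
                  colour = "phase") +
    ggplot2::theme_minimal()
  if (!is.null(data)) {
    check_experiment_table(data)
    pts <- dplyr::filter(data, .data$dose_gy == !!dose_gy)
    pts$phase <- factor(toupper(pts$phase), levels = c("G1", "S", "G2", "M"))
    pts$value <- pts$percent / 100 * scale
    p <- p + ggplot2::geom_point(data = pts)
    if ("sem" %in% names(pts)) {
      pts$err <- pts$sem / 100 * scale
      p <- p + ggplot2::geom_errorbar(
        data = pts, ggplot2::aes(ymin = .data$value - .data$err,
                                 ymax = .data$value + .data$err), width = 1)
    }
  }
  p
}

#' @rdname evolve_to_sdd
#' @param object An `sdd_result`.
#' @param ... Unused.
#' @export
autoplot.sdd_result <- function(object, ...) {
  plot_timecourse(object$trajectory) +
    ggplot2::geom_vline(xintercept = object$t_sdd, linetype = 3) +
    ggplot2::labs(title = sprintf("Approach to the steady DNA distribution (t_SDD = %.2f h)",
                                  object$t_sdd))
}
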