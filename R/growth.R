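#' Fit an exponential growth curve and estimate the doubling time
#'
#' Fits `N(t) = N0 exp(gamma t)` to cell counts by nonlinear least squares
#' and derives the population doubling time `T_D = ln 2 / gamma` with a 95%
#' confidence interval from the parameter covariance (delta method).
#'
#' @param counts Data frame with columns `time_h` and `count` (one row per
#'   measurement; replicates are simply extra rows). At least 3 rows with
#'   positive counts.
#' @return An object of class `growth_fit` with elements `n0`, `gamma`,
#'   `t_d`, `ci95` (on `t_d`), and the underlying `nls` fit. A non-positive
#'   fitted growth rate triggers a warning and `t_d = Inf`.
#' @examples
#' tc <- generate_synthetic_growth(1e5, log(2) / 38.4, c(6, 16, 24, 48, 72), cv = 0)
#' fit_growth_curve(tc)$t_d
#' @export
fit_growth_curve <- function(counts) {
  if (!is.data.frame(counts) || !all(c("time_h", "count") %in% names(counts))) {
    abort("`counts` must be a data frame with columns time_h and count")
  }
  counts <- dplyr::filter(counts, !is.na(.data$count))
  if (nrow(counts) < 3) abort("need at least 3 count measurements")
  if (any(counts$count <= 0)) abort("all counts must be > 0")
  # log-linear start values, then proper nls on the original scale
  lmfit <- stats::lm(log(count) ~ time_h, data = counts)
  start <- list(n0 = exp(coef(lmfit)[[1]]), gamma = coef(lmfit)[[2]])
  # scaleOffset makes the convergence test robust to zero-residual data
  fit <- nls(count ~ n0 * exp(gamma * time_h), data = counts, start = start,
             control = stats::nls.control(maxiter = 100, scaleOffset = 1))
  gamma <- coef(fit)[["gamma"]]
  n0 <- coef(fit)[["n0"]]
  if (gamma <= 0) {
    warn("fitted growth rate is non-positive; doubling time reported as Inf")
    t_d <- Inf
    ci <- c(NA_real_, NA_real_)
  } else {
    t_d <- log(2) / gamma
    se_gamma <- sqrt(vcov(fit)["gamma", "gamma"])
    se_td <- log(2) / gamma^2 * se_gamma
    ci <- t_d + c(-1, 1) * stats::qt(0.975, stats::df.residual(fit)) * se_td
  }
  structure(list(n0 = n0, gamma = gamma, t_d = t_d, ci95 = ci,
                 fit = fit, data = tibble::as_tibble(counts)),
            class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf("<growth_fit> N0 = %.4g, gamma = %.5g 1/h\n", x$n0, x$gamma))
  cat(sprintf("  doubling time T_D = %.3g h (95%% CI [%.3g, %.3g])\n",
              x$t_d, x$ci95[1], x$ci95[2]))
  invisible(x)
}

#' @rdname fit_growth_curve
#' @param x A `growth_fit` object.
#' @param ... Unused.
#' @export
tidy.growth_fit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble::tibble(term = rownames(s), estimate = s[, 1], std.error = s[, 2],
                 statistic = s[, 3], p.value = s[, 4])
}

#' @rdname fit_growth_curve
#' @export
glance.growth_fit <- function(x, ...) {
  tibble::tibble(t_d = x$t_d, t_d_low = x$ci95[1], t_d_high = x$ci95[2],
                 gamma = x$gamma, n0 = x$n0,
                 sigma = summary(x$fit)$sigma, nobs = nrow(x$data))
}

#' @rdname fit_growth_curve
#' @param object A `growth_fit` object.
#' @export
autoplot.growth_fit <- function(object, ...) {
  grid <- tibble::tibble(time_h = seq(min(object$data$time_h),
                                      max(object$data$time_h), length.out = 200))
  grid$count <- object$n0 * exp(object$gamma * grid$time_h)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$time_h, y = .data$count)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "time (h)", y = "cell count",
                  title = sprintf("Exponential growth fit: T_D = %.1f h", object$t_d)) +
    ggplot2::theme_minimal()
}
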