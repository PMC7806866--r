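#' Shape parameters for DNA-content profile reconstruction
#'
#' Gaussian shape parameters used to turn compartment counts into a
#' flow-cytometry-like DNA histogram. Relative DNA content is scaled so G1
#' cells sit at `x = 1` and G2/M cells at `x = 2`. The G1 variance default
#' of 0.05 mimics the experimental spread of a G1 peak (~5% of the mean);
#' the G2/M variance defaults to twice that. The grid upper limit `x_max`
#' stands in for infinity: with the defaults the Gaussian mass lost beyond
#' it is below 1e-6 of the total.
#'
#' @param mu1 Mean relative DNA content in G1 (default 1).
#' @param mu2,mu_m Means for G2 and M (default 2).
#' @param theta1_sq G1 variance (default 0.05).
#' @param theta2_sq G2/M variance (default `2 * theta1_sq`).
#' @param x_max Upper limit of the DNA-content axis (default 4).
#' @param dx Grid spacing (default 0.01).
#' @return An object of class `profile_shape`.
#' @export
profile_shape <- function(mu1 = 1, mu2 = 2, mu_m = 2, theta1_sq = 0.05,
                          theta2_sq = 2 * theta1_sq, x_max = 4, dx = 0.01) {
  if (!(mu1 > 0 && mu1 < mu2 && mu2 <= x_max)) abort("need 0 < mu1 < mu2 <= x_max")
  if (theta1_sq <= 0 || theta2_sq <= 0) abort("variances must be > 0")
  if (dx <= 0 || dx >= x_max) abort("`dx` must be in (0, x_max)")
  tail_mass <- stats::pnorm(x_max, mu2, sqrt(theta2_sq), lower.tail = FALSE)
  if (tail_mass > 1e-6) {
    warn(sprintf("x_max = %g truncates %.2g of the G2/M Gaussian mass; increase it", x_max, tail_mass))
  }
  structure(list(mu1 = mu1, mu2 = mu2, mu_m = mu_m, theta1_sq = theta1_sq,
                 theta2_sq = theta2_sq, x_max = x_max, dx = dx),
            class = "profile_shape")
}

#' Reconstruct per-phase DNA-content profiles from a population state
#'
#' Superimposes Gaussian densities on the compartment counts: G1 cells at
#' mean `mu1` with variance `theta1_sq`; G2 and M cells at mean 2 with
#' variance `theta2_sq`; each S-phase age bin at a mean shifted linearly
#' from `mu1` to `mu2` with age (`mu1 + (mu2 - mu1) * tau / T_S`, where
#' `T_S = 1/g`) and a variance interpolated linearly between `theta1_sq`
#' and `theta2_sq`. The total profile is the pointwise sum and is what a
#' cytometer's DNA channel would show for this population.
#'
#' @param state An [age_state()].
#' @param shape A [profile_shape()].
#' @param g DNA synthesis rate (1/h) that sized the S delay line of `state`.
#' @param dt Time step used to build `state` (to map age bins to hours).
#' @return A `dna_profile`: a tibble with columns `x`, `g1`, `s`, `g2`,
#'   `m`, `total` (densities per unit DNA content).
#' @export
phase_profiles <- function(state, shape = profile_shape(), g, dt = 0.05) {
  stopifnot(inherits(state, "age_state"), inherits(shape, "profile_shape"))
  nb <- length(state$ns)
  if (nb != n_age_bins(g, dt)) {
    abort("`state` S delay line does not match `g` and `dt`")
  }
  x <- seq(0, shape$x_max, by = shape$dx)
  t_s <- 1 / g
  g1 <- state$n1 * dnorm(x, shape$mu1, sqrt(shape$theta1_sq))
  g2 <- state$n2 * dnorm(x, shape$mu2, sqrt(shape$theta2_sq))
  m <- state$nm * dnorm(x, shape$mu_m, sqrt(shape$theta2_sq))
  tau <- (seq_len(nb) - 1L) * dt
  means <- shape$mu1 + (shape$mu2 - shape$mu1) * tau / t_s
  vars <- shape$theta1_sq + (shape$theta2_sq - shape$theta1_sq) * tau / t_s
  # grid x (rows) by age bin (cols) Gaussian matrix times bin counts
  dens <- vapply(seq_len(nb), function(j) dnorm(x, means[j], sqrt(vars[j])),
                 numeric(length(x)))
  s <- as.numeric(dens %*% state$ns)
  prof <- tibble::tibble(x = x, g1 = g1, s = s, g2 = g2, m = m,
                         total = g1 + s + g2 + m)
  counts <- c(state$n1, sum(state$ns), state$n2, state$nm)
  masses <- vapply(c("g1", "s", "g2", "m"), function(p) trapz(x, prof[[p]]),
                   numeric(1))
  rel_err <- abs(masses - counts) / pmax(counts, .Machine$double.eps)
  if (any(counts > 0 & rel_err > 1e-3)) {
    warn(sprintf("profile grid too coarse: worst phase mass error %.2g (decrease dx or widen x_max)",
                 max(rel_err[counts > 0])))
  }
  structure(prof, class = c("dna_profile", class(prof)),
            shape = shape, counts = setNames(counts, PHASES))
}

trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

#' Bin a DNA profile into a cytometer-style histogram
#'
#' Integrates the total density over `n_bins` uniform bins on
#' `[0, x_max]`; total mass is preserved.
#'
#' @param profile A `dna_profile` from [phase_profiles()].
#' @param n_bins Number of bins (>= 10).
#' @param per_phase Also emit per-phase bin masses (default TRUE).
#' @return A tibble with `bin_left`, `bin_right`, per-phase masses (if
#'   requested) and `total`.
#' @export
total_histogram <- function(profile, n_bins = 400, per_phase = TRUE) {
  stopifnot(inherits(profile, "dna_profile"))
  if (n_bins < 10) abort("`n_bins` must be >= 10")
  x <- profile$x
  x_max <- max(x)
  edges <- seq(0, x_max, length.out = n_bins + 1)
  bin_mass <- function(y) {
    cum <- c(0, cumsum(diff(x) * (head(y, -1) + tail(y, -1)) / 2))
    ci <- stats::approx(x, cum, xout = edges, rule = 2)$y
    diff(ci)
  }
  out <- tibble::tibble(bin_left = head(edges, -1), bin_right = tail(edges, -1))
  if (per_phase) {
    for (p in c("g1", "s", "g2", "m")) out[[p]] <- bin_mass(profile[[p]])
    out$total <- out$g1 + out$s + out$g2 + out$m
  } else {
    out$total <- bin_mass(profile$total)
  }
  out
}

#' @rdname phase_profiles
#' @param object A `dna_profile`.
#' @param ... Unused.
#' @export
autoplot.dna_profile <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              cols = c("g1", "s", "g2", "m", "total"),
                              names_to = "phase", values_to = "density")
  long$phase <- factor(toupper(long$phase), levels = c("G1", "S", "G2", "M", "TOTAL"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$x, y = .data$density,
                                     colour = .data$phase)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "relative DNA content", y = "density",
                  title = "Reconstructed DNA-content profile") +
    ggplot2::theme_minimal()
}
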