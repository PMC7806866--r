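test_that("Steel's formulas convert fractions and doubling time to phase durations", {
  f <- c(f_g1 = 0.6106, f_s = 0.3007, f_g2 = 0.0807, f_m = 0.0080)
  times <- steel_phase_times(f, t_d = 38.4)

  # independent oracle: direct evaluation of the closed forms
  t_m <- 38.4 * 0.0080
  t_g2 <- 38.4 * log2(0.0807 + 0.0080 + 1) - t_m
  t_s <- 38.4 * log2(0.3007 + 0.0807 + 0.0080 + 1) - t_g2 - t_m
  expect_equal(times$t_m, t_m)
  expect_equal(times$t_g2, t_g2)
  expect_equal(times$t_s, t_s)
  expect_equal(times$t_g1, 38.4 - t_s - t_g2 - t_m)
  # frozen values for the reference composition
  expect_equal(unlist(times[1, 1:4]), c(t_g1 = 20.182, t_s = 13.509,
                                        t_g2 = 4.401, t_m = 0.3072),
               tolerance = 1e-4)

  # identity: durations always sum to t_d exactly
  expect_equal(times$t_g1 + times$t_s + times$t_g2 + times$t_m, 38.4)
  set.seed(5)
  for (i in 1:10) {
    fr <- runif(4)
    fr <- fr / sum(fr)
    td <- runif(1, 10, 80)
    tt <- steel_phase_times(setNames(fr, paste0("f_", c("g1", "s", "g2", "m"))), td)
    expect_equal(tt$t_g1 + tt$t_s + tt$t_g2 + tt$t_m, td)
  }

  # everything in G1
  all_g1 <- steel_phase_times(c(f_g1 = 1, f_s = 0, f_g2 = 0, f_m = 0), 17)
  expect_equal(unlist(all_g1[1, 1:4]), c(t_g1 = 17, t_s = 0, t_g2 = 0, t_m = 0))

  # with properly normalised fractions every duration is non-negative by
  # construction; an over-complete composition (sum > 1) breaks the G1 term
  expect_error(
    suppressWarnings(
      steel_phase_times(c(f_g1 = 0, f_s = 0.6, f_g2 = 0.5, f_m = 0.4), 20)),
    "negative duration")
})

test_that("durations invert to rates (reciprocal relation, death rates subtracted)", {
  f <- c(f_g1 = 0.6106, f_s = 0.3007, f_g2 = 0.0807, f_m = 0.0080)
  r <- steel_rates(f, 38.4)
  expect_equal(signif(r$k1, 3), 0.0496)
  expect_equal(signif(r$g, 3), 0.0740)
  expect_equal(signif(r$k2, 3), 0.227)

  expect_equal(unlist(rates_from_phase_times(
    c(t_g1 = 1, t_s = 1, t_g2 = 1, t_m = 1))[c("k1", "g", "k2", "b")]),
    c(k1 = 1, g = 1, k2 = 1, b = 1))

  r2 <- rates_from_phase_times(c(t_g1 = 2, t_s = 1, t_g2 = 1, t_m = 1), mu_g1 = 0.1)
  expect_equal(r2$k1, 0.4)

  # round trip: times -> rates -> implied durations
  times <- steel_phase_times(f, 38.4)
  rr <- rates_from_phase_times(times)
  expect_equal(1 / rr$k1, times$t_g1)
  expect_equal(1 / rr$g, times$t_s)
  expect_equal(implied_cycle_length(rr), 38.4)
})

test_that("sham averages over the exponential window match the reference dataset", {
  avg <- average_fractions(load_fixture("table1"))
  expect_equal(round(100 * avg$f_g1, 2), 61.06)
  expect_equal(round(100 * avg$f_s, 2), 30.07)
  expect_equal(round(100 * avg$f_g2, 2), 8.07)
  expect_equal(round(100 * avg$f_m, 2), 0.80)
  # combined uncertainties (RMS of the per-time SEMs)
  expect_equal(round(100 * avg$sem_g1, 2), 1.59)
  expect_equal(round(100 * avg$sem_m, 2), 0.28)
})

test_that("growth-curve fit recovers the doubling time", {
  gamma <- log(2) / 38.4
  clean <- generate_synthetic_growth(1e5, gamma, times = c(6, 16, 24, 48, 72), cv = 0)
  fit <- fit_growth_curve(clean)
  expect_equal(fit$t_d, 38.4, tolerance = 1e-8)
  expect_equal(fit$n0, 1e5, tolerance = 1e-6)
  expect_equal(glance(fit)$t_d, fit$t_d)
  expect_identical(nrow(tidy(fit)), 2L)

  # the doubling-time relation itself, to the printed precision
  expect_equal(round(log(2) / 0.0180489, 1), 38.4)

  expect_error(fit_growth_curve(clean[1:2, ]), "at least 3")
})

test_that("growth-fit confidence intervals have close to nominal coverage", {
  gamma <- log(2) / 38.4
  covered <- 0L
  for (seed in 1:100) {
    counts <- generate_synthetic_growth(1e5, gamma, cv = 0.1,
                                        n_replicates = 6, seed = seed)
    fit <- fit_growth_curve(counts)
    if (fit$ci95[1] <= 38.4 && 38.4 <= fit$ci95[2]) covered <- covered + 1L
  }
  expect_gte(covered, 90L)
})

test_that("chi-square objective is the standard weighted sum of squares", {
  d <- tibble::tibble(time_h = 0, p_g1 = 61.06, p_s = 30.07, p_g2 = 8.07,
                      p_m = 0.80, sem_g1 = 1.59, sem_s = 1.52,
                      sem_g2 = 1.01, sem_m = 0.28)
  expect_equal(chi_square_objective(d, d), 0)

  # one standardised residual: ((62 - 61.06) / 1.59)^2
  m <- dplyr::mutate(d, p_g1 = 62)
  base <- chi_square_objective(m, d)
  expect_equal(base, (62 - 61.06)^2 / 1.59^2)
  expect_equal(round(base, 4), 0.3495)

  # doubling every sigma divides the objective by 4
  d2 <- dplyr::mutate(d, dplyr::across(dplyr::starts_with("sem_"), ~ 2 * .x))
  expect_equal(chi_square_objective(m, d2), base / 4)

  expect_error(chi_square_objective(m, dplyr::mutate(d, sem_s = 0)), "SEMs must be > 0")
})

test_that("sequential chi-square fit matches the reference calibration", {
  fit <- fit_unperturbed(load_fixture("table1"), t_d = T_D_REF)
  expect_lt(abs(fit$rates$k1 - 0.0429) / 0.0429, 0.10)
  expect_lt(abs(fit$rates$k2 - 0.2347) / 0.2347, 0.10)
  expect_lte(fit$objective, fit$objective_init)
  expect_true(fit$admissible)
  # bounds respected
  td <- tidy(fit)
  expect_true(all(td$estimate >= td$lower & td$estimate <= td$upper))
  # the per-cycle trace never increases
  expect_true(all(diff(fit$trace) <= 1e-9))
})

test_that("fit recovers exactly a parameter set whose fractions generated the data", {
  truth <- rate_params(0.045, 0.08, 0.22, 3)
  f <- 100 * sdd_fractions(truth, 0.05)
  wide <- tibble::tibble(time_h = c(0, 6, 16, 24),
                         p_g1 = f[["g1"]], p_s = f[["s"]], p_g2 = f[["g2"]],
                         p_m = f[["m"]], sem_g1 = 1.59, sem_s = 1.52,
                         sem_g2 = 1.01, sem_m = 0.28)
  fit <- fit_unperturbed(wide, t_d = implied_cycle_length(truth),
                         init = truth, fix_b_at = NULL)
  expect_lt(fit$objective, 1e-8)
  expect_equal(fit$rates$k1, truth$k1, tolerance = 1e-3)
  expect_equal(fit$rates$k2, truth$k2, tolerance = 1e-3)

  # minimiser contract on noisy synthetic datasets: never worse than the start
  set.seed(31)
  for (i in 1:5) {
    tr <- random_rates()
    tab <- generate_synthetic_timecourse(tr, sample_times = c(0, 6, 16, 24),
                                         seed = 100 + i)
    init <- steel_rates(average_fractions(tab)[, 1:4], implied_cycle_length(tr))
    init <- rate_params(min(max(init$k1, 0.03), 0.06), min(max(init$g, 0.05), 0.5),
                        min(max(init$k2, 0.05), 0.5), min(max(init$b, 2), 5))
    fit_i <- tryCatch(
      fit_unperturbed(tab, t_d = implied_cycle_length(tr), init = init),
      radcycle_inadmissible_fit = function(e) e$best)
    expect_lte(fit_i$objective, fit_i$objective_init + 1e-9)
  }
})

test_that("relative differences reproduce the published comparison table", {
  expect_equal(round(relative_difference(22.47, 7.04)$delta, 2), 2.19)
  expect_equal(round(relative_difference(82.37, 62.62)$delta, 2), 0.32)
  expect_equal(relative_difference(5, 5)$delta, 0)
  expect_error(relative_difference(3, 0), "must be > 0")

  rd <- relative_differences(load_fixture("table1"))
  t2 <- load_fixture("table2")
  j <- dplyr::inner_join(rd, t2, by = c("time_h", "dose_gy", "phase"),
                         suffix = c("_calc", "_pub"))
  expect_identical(nrow(j), 40L)
  # every published cell agrees with the direct ratio of the percentages to
  # the printed precision (0.0105 absorbs float fuzz on exactly-0.01 gaps)
  expect_true(all(abs(round(j$delta_calc, 2) - j$delta_pub) <= 0.0105))
})
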