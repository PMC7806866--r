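test_that("transition matrix implements the finite-difference update", {
  tm <- build_transition_matrix(steel_ref_rates(), dt = 0.05)
  A <- tm$entries
  n <- nrow(A)

  # delay line sized by T_S = 1/g: round(13.514 / 0.05) + 1 = 271 bins
  expect_identical(tm$n_age_bins, 271L)
  expect_identical(n, 274L)

  expect_equal(A[1, 1], 1 - 0.0496 * 0.05)          # G1 diagonal 0.99752
  expect_equal(A[1, n], 2 * 3.2577 * 0.05)          # M -> G1 entry 0.32577
  expect_equal(A[2, 1], 0.0496 * 0.05)              # G1 -> first S age bin
  expect_equal(A[n - 1, tm$n_age_bins + 1], 1)      # last S bin flows wholly into G2
  expect_equal(A[n - 1, n - 1], 1 - 0.2272 * 0.05)
  expect_equal(A[n, n - 1], 0.2272 * 0.05)
  expect_equal(A[n, n], 1 - 3.2577 * 0.05)

  # columns conserve cells except the M column, where division adds b*dt
  cs <- colSums(A)
  expect_equal(cs[-n], rep(1, n - 1))
  expect_equal(cs[n], 1 + 3.2577 * 0.05)
  expect_true(all(A >= 0 & A <= 2))

  # with no transitions at all, the matrix is purely conservative
  tm0 <- build_transition_matrix(rate_params(0, 0.1, 0, 0), dt = 0.05)
  expect_equal(colSums(tm0$entries), rep(1, nrow(tm0$entries)))

  # boundary of stability: complete one-step transfer out of G1
  tmb <- build_transition_matrix(rate_params(1 / 0.05, 0.1, 0, 0), dt = 0.05)
  expect_equal(tmb$entries[1, 1], 0)

  expect_error(build_transition_matrix(rate_params(0.05, 0.1, 0.2, 30), dt = 0.05),
               "stability violation.*`b`")
})

test_that("stepping transfers mass exactly as the matrix prescribes", {
  rates <- steel_ref_rates()
  tm <- build_transition_matrix(rates, dt = 0.05)

  zero <- initial_state_g1(rates, 0.05, n_total = 0)
  expect_equal(total_cells(step_population(zero, tm)), 0)

  # one hand-evaluated matrix-vector product from the all-in-G1 start
  s1 <- step_population(initial_state_g1(rates, 0.05), tm)
  expect_equal(s1$n1, 0.99752)
  expect_equal(s1$ns[1], 0.00248)
  expect_equal(s1$t, 0.05)

  other <- build_transition_matrix(rate_params(0.05, 0.2, 0.2, 3), 0.05)
  expect_error(step_population(s1, other), "dimension mismatch")
})

test_that("cell number is conserved without division and never goes negative", {
  # b = 0, mu = 0: every column sums to 1, so the total is invariant
  rates <- rate_params(k1 = 0.05, g = 0.2, k2 = 0.2, b = 0)
  tm <- build_transition_matrix(rates, dt = 0.05)
  u <- state_vector(initial_state_g1(rates, 0.05, n_total = 3.7))
  A <- tm$entries
  for (i in seq_len(1e4)) u <- as.numeric(A %*% u)
  expect_equal(sum(u), 3.7, tolerance = 1e-12)
  expect_true(all(u >= 0))

  # non-negativity for random valid matrices and random non-negative states
  set.seed(11)
  for (i in 1:5) {
    r <- random_rates()
    tm <- build_transition_matrix(r, 0.05)
    u <- runif(nrow(tm$entries))
    for (s in 1:200) u <- as.numeric(tm$entries %*% u)
    expect_true(all(u >= 0))
  }
})

test_that("population growth is exponential with the dominant eigenvalue's rate", {
  rates <- steel_ref_rates()
  tc <- simulate_timecourse(rates, horizon = 200)
  expect_true(all(diff(tc$n_total) > -1e-12))
  lam <- dominant_mode(build_transition_matrix(rates, 0.05))$growth_factor
  # asymptotic slope of log(total) per step
  late <- tc$n_total[tc$time_h >= 150]
  slope <- mean(diff(log(late)))
  expect_equal(slope, log(lam), tolerance = 1e-6)
})

test_that("SDD convergence matches the published criterion and is lag-limited", {
  res <- evolve_to_sdd(steel_ref_rates())
  expect_equal(res$t_sdd, 40.45, tolerance = 1e-9)
  expect_equal(sum(res$fractions), 1, tolerance = 1e-9)
  expect_gte(res$t_sdd, res$config$sdd_lag)

  # starting on the dominant eigenvector, the first admissible check passes
  dm <- dominant_mode(build_transition_matrix(steel_ref_rates(), 0.05))
  sdd_state <- evolve_to_sdd(steel_ref_rates(), sim_config(sdd_tol = 1e-10),
                             initial = NULL)$state
  sdd_state$t <- 0
  res2 <- evolve_to_sdd(steel_ref_rates(), initial = sdd_state)
  expect_equal(res2$t_sdd, res2$config$sdd_lag)

  expect_error(evolve_to_sdd(steel_ref_rates(), sim_config(max_time = 10)),
               "no SDD convergence.*residual")
})

test_that("dominant mode agrees with long-run simulation and the closed form", {
  # no division: the population neither grows nor shrinks
  tm0 <- build_transition_matrix(rate_params(0, 0.1, 0, 0), 0.05)
  dm0 <- dominant_mode(tm0)
  expect_equal(dm0$growth_factor, 1)
  expect_identical(dm0$doubling_time, Inf)

  rates <- steel_ref_rates()
  dm <- dominant_mode(build_transition_matrix(rates, 0.05))
  # Steel's formulas make the phase times sum to T_D, so the model's
  # intrinsic doubling time approximates the measured 38.4 h
  expect_lt(abs(dm$doubling_time - T_D_REF) / T_D_REF, 0.1)
  # independent oracle: doubling time from the slope of log(total cells)
  tc <- simulate_timecourse(rates, horizon = 200)
  late <- tc$n_total[tc$time_h >= 150]
  td_slope <- 0.05 * log(2) / mean(diff(log(late)))
  expect_equal(dm$doubling_time, td_slope, tolerance = 1e-4)

  # eigen decomposition, characteristic-root closed form and time stepping
  # all give the same steady composition
  set.seed(23)
  for (i in 1:6) {
    r <- random_rates()
    dm_i <- dominant_mode(build_transition_matrix(r, 0.05))
    f_root <- sdd_fractions(r, 0.05)
    expect_equal(dm_i$sdd_fractions, f_root, tolerance = 1e-9)
    f_sim <- evolve_to_sdd(r, sim_config(sdd_tol = 1e-8))$fractions
    expect_equal(unname(dm_i$sdd_fractions), unname(f_sim), tolerance = 1e-3)
  }
})

test_that("steady fractions sit within 3 SEM of the sham averages", {
  # the Steel-initialised model is close to, but not exactly at, the
  # measured composition
  f <- 100 * sdd_fractions(steel_ref_rates(), 0.05)
  avg <- average_fractions(load_fixture("table1"))
  meas <- 100 * unlist(avg[paste0("f_", c("g1", "s", "g2", "m"))])
  sems <- 100 * unlist(avg[paste0("sem_", c("g1", "s", "g2", "m"))])
  expect_true(all(abs(f - meas) <= 3 * sems))
  expect_gt(max(abs(f - meas) / sems), 0.5)  # not exact, only compatible
})

test_that("time courses stitch exactly across rate breakpoints", {
  rates <- rate_params(0.05, 0.2, 0.2, 3)
  sched <- perturbation_schedule(
    tibble::tibble(t_start = c(0, 10), t_end = c(10, Inf),
                   k1 = c(1, 0.2), k2 = c(0.5, 1)))
  full <- simulate_timecourse(rates, horizon = 20, schedule = sched)

  # manual stitching: run segment 1, restart segment 2 from its end state
  r1 <- apply_multipliers(rates, schedule_segments(sched)[1, ])
  tm1 <- build_transition_matrix(r1, 0.05)
  st <- initial_state_g1(rates, 0.05)
  for (i in 1:200) st <- step_population(st, tm1)
  r2 <- apply_multipliers(rates, schedule_segments(sched)[2, ])
  tm2 <- build_transition_matrix(r2, 0.05)
  for (i in 1:200) st <- step_population(st, tm2)
  f_end <- phase_fractions(st)
  expect_equal(unname(unlist(full[nrow(full), FRAC_COLS])), unname(f_end),
               tolerance = 1e-12)

  # constant rates started exactly on the dominant eigenvector stay put
  tm <- build_transition_matrix(rates, 0.05)
  e <- eigen(tm$entries)
  v <- Re(e$vectors[, which.max(Mod(e$values))])
  v <- pmax(v / sum(v), 0)
  eig_state <- state_from_vector(v, t = 0)
  flat <- simulate_timecourse(rates, horizon = 10, initial = eig_state)
  expect_lt(max(abs(flat$f_g1 - flat$f_g1[1])), 1e-9)

  # zero horizon returns the initial fractions only
  z <- simulate_timecourse(rates, horizon = 0)
  expect_identical(nrow(z), 1L)
  expect_equal(z$f_g1, 1)
})
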