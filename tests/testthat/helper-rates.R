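# Reference IMR90 calibration values used across the suite:
# Steel-initialised rates and the chi-square best fit for the sham data.
steel_ref_rates <- function() rate_params(k1 = 0.0496, g = 0.0740, k2 = 0.2272, b = 3.2577)
best_fit_rates <- function() rate_params(k1 = 0.0429, g = 0.0796, k2 = 0.2347, b = 2.3655)
T_D_REF <- 38.4

sham_wide <- function(times = c(0, 6, 16, 24)) {
  as_percent_wide(load_fixture("table1"), dose_gy = 0, times = times)
}

# random kinetically plausible parameter set (moderate S duration so the
# delay line stays small enough for fast stepping)
random_rates <- function() {
  rate_params(k1 = runif(1, 0.03, 0.06), g = runif(1, 0.07, 0.3),
              k2 = runif(1, 0.1, 0.4), b = runif(1, 2, 4.5))
}

# table of per-dose experimental percentages and sems at the five
# post-irradiation sampling times, as matrices for envelope checks
dose_matrices <- function(dose) {
  tab <- load_fixture("table1")
  wide <- as_percent_wide(tab, dose_gy = dose, times = c(6, 16, 24, 48, 72))
  list(times = wide$time_h,
       percent = as.matrix(wide[paste0("p_", c("g1", "s", "g2", "m"))]),
       sem = as.matrix(wide[paste0("sem_", c("g1", "s", "g2", "m"))]))
}
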