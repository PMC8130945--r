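# Fixtures built in code: small life tables, degenerate generator configs,
# and shared oracle helpers.

# constant-rate life table (same rate in every cell)
const_lifetable <- function(m, ages = 0:110, years = 1970:2070) {
  rates <- array(m, dim = c(length(ages), length(years), 2L))
  new_lifetable(rates, min(ages), max(ages), min(years), max(years))
}

zero_lifetable <- function(...) const_lifetable(0, ...)

# life table whose rate depends only on age, from a named vector rate_by_age
age_lifetable <- function(rate_by_age, years = 1990:2060) {
  ages <- as.integer(names(rate_by_age))
  stopifnot(identical(ages, min(ages):max(ages)))
  rates <- array(rep(rate_by_age, times = 2L * length(years)),
                 dim = c(length(ages), length(years), 2L))
  new_lifetable(rates, min(ages), max(ages), min(years), max(years))
}

# trigam with no excess hazard at all
null_trigam <- function() trigam_params(A = 0, H = 0)

# one-row cohort
one_case <- function(age_dx, year_dx, futime, status = "alive", sex = "female") {
  new_cohort(data.frame(id = "c1", sex = sex, age_dx = age_dx,
                        year_dx = year_dx, futime = futime, status = status,
                        morph = 8720L, site = "C69.3",
                        stringsAsFactors = FALSE),
             study_end = year_dx + futime + 1)
}

# degenerate generator config: every case same sex/age/year, no censoring
# pressure until study_end
pinned_config <- function(n, seed, trigam = trigam_params(), age = 60,
                          year = 2000, study_end = 2045, misreport = 0) {
  gen_config(n_cases = n, seed = seed, age_mean = age, age_sd = 1,
             age_range = c(age, age), sex_ratio = 1,
             dx_year_range = c(year, year + 1e-9), trigam = trigam,
             misreport_frac = misreport, study_end = study_end)
}

# brute-force expected deaths for one case by fine-grid integration of
# get_rate along the Lexis diagonal (independent of .lexis_segments)
brute_expected <- function(table, sex, age_dx, year_dx, t_lo, t_hi,
                           dt = 1 / 2048) {
  grid <- seq(t_lo, t_hi, by = dt)
  if (grid[length(grid)] < t_hi) grid <- c(grid, t_hi)
  mids <- (grid[-1] + grid[-length(grid)]) / 2
  sum(get_rate(table, sex, age_dx + mids, year_dx + mids) * diff(grid))
}

# standard error of a relative-survival point: observed KM error (from its
# log-log CI width) plus matched-arm binomial simulation error
rs_combined_se <- function(os_curve, exp_curve, n_sim, t) {
  o <- eval_at(os_curve, t)
  e <- eval_at(exp_curve, t)
  se_o <- (o$hi - o$lo) / (2 * stats::qnorm(0.975))
  se_e <- sqrt(e$value * (1 - e$value) / n_sim)
  sqrt((se_o / e$value)^2 + (o$value * se_e / e$value^2)^2)
}
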