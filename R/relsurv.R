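#' Simulate matched "normal" counterparts through the life table
#'
#' For each case, `k` disease-free simulants start at the case's (sex, age at
#' diagnosis, year of diagnosis) and are stepped forward one year at a time,
#' incrementing age and calendar year together and refreshing the background
#' rate `m` at each step. Within a step, death occurs with probability
#' `1 - exp(-m)`; when it does, the time of death within the year is drawn
#' uniformly over that year. A simulant reaching age 120 dies at the cap
#' (negligible mass; guarantees termination). The simulation is reproducible
#' from `seed`.
#'
#' This yearly-step scheme is deliberately the registry-simulation
#' convention, not exact piecewise-constant-hazard inversion; its small
#' discretisation bias is bounded in the package tests.
#'
#' @param cohort a [new_cohort()].
#' @param table a [new_lifetable()] (ages and years clamp at the table
#'   edges).
#' @param k matched simulants per case, `>= 1`.
#' @param seed integer RNG seed.
#' @param age_cap forced-death age in years.
#' @return An `expected_cohort` data frame with one row per simulant:
#'   `case_id`, `sex`, `age_start`, `year_start`, `t_death` (years from
#'   start); attributes `k` and `seed`.
#' @export
sim_expected <- function(cohort, table, k = 3, seed = 1, age_cap = 120) {
  stopifnot(inherits(cohort, "cohort"), inherits(table, "lifetable"), k >= 1)
  set.seed(seed)
  n <- nrow(cohort)
  case_id <- rep(cohort$id, each = k)
  sex <- rep(cohort$sex, each = k)
  age0 <- rep(cohort$age_dx, each = k)
  year0 <- rep(cohort$year_dx, each = k)
  N <- n * k
  t_death <- rep(NA_real_, N)
  alive <- rep(TRUE, N)
  step <- 0L
  while (any(alive)) {
    idx <- which(alive)
    at_cap <- age0[idx] + step >= age_cap
    if (any(at_cap)) {
      cap_idx <- idx[at_cap]
      t_death[cap_idx] <- age_cap - age0[cap_idx]
      alive[cap_idx] <- FALSE
      idx <- idx[!at_cap]
      if (!length(idx)) break
    }
    m <- get_rate(table, sex[idx], age0[idx] + step, year0[idx] + step)
    dies <- stats::runif(length(idx)) < 1 - exp(-m)
    if (any(dies)) {
      die_idx <- idx[dies]
      t_death[die_idx] <- step + stats::runif(length(die_idx))
      alive[die_idx] <- FALSE
    }
    step <- step + 1L
  }
  structure(data.frame(case_id = case_id, sex = sex, age_start = age0,
                       year_start = year0, t_death = t_death,
                       stringsAsFactors = FALSE),
            k = k, seed = seed, class = c("expected_cohort", "data.frame"))
}

#' Expected survival of the simulated matched cohort
#'
#' Empirical survival step function of the simulated death times (there is
#' no censoring in the matched arm). No analytic CI is attached: the
#' simulation error shrinks with `k` and the curve carries `k` as an
#' attribute instead.
#'
#' @param exp_cohort a [sim_expected()] result.
#' @param t_grid optional evaluation grid; if supplied, the curve is
#'   evaluated via [eval_at()] and the data frame is returned instead.
#' @return A [new_step_survival()] of kind `"survival"` (or its [eval_at()]
#'   data frame when `t_grid` is given).
#' @export
expected_survival <- function(exp_cohort, t_grid = NULL) {
  stopifnot(inherits(exp_cohort, "expected_cohort"), nrow(exp_cohort) >= 1)
  N <- nrow(exp_cohort)
  times <- sort(unique(exp_cohort$t_death))
  d <- tabulate(match(exp_cohort$t_death, times), nbins = length(times))
  surv <- 1 - cumsum(d) / N
  curve <- new_step_survival(times, surv,
                             n_risk = N - cumsum(d) + d, n_event = d,
                             kind = "survival")
  attr(curve, "k") <- attr(exp_cohort, "k")
  if (is.null(t_grid)) curve else eval_at(curve, t_grid)
}

#' Relative survival: observed over expected
#'
#' `RS(t) = S_obs(t) / S_exp(t)` on a time grid, with confidence bounds
#' taken as the observed Kaplan-Meier bounds divided by the (high-`k`,
#' near-deterministic) expected curve. Values may exceed 1. Grid points
#' where the expected survival is 0 are dropped with a warning.
#'
#' @param observed a [km_fit()] overall-survival curve.
#' @param expected an [expected_survival()] curve.
#' @param t_grid evaluation times in years.
#' @return Data frame of class `rel_survival`: `time`, `rs`, `lo`, `hi`,
#'   `extrapolated`.
#' @export
relative_survival <- function(observed, expected, t_grid) {
  stopifnot(inherits(observed, "step_survival"),
            inherits(expected, "step_survival"))
  o <- eval_at(observed, t_grid)
  e <- eval_at(expected, t_grid)
  bad <- e$value <= 0
  if (any(bad)) {
    warning("expected survival is 0 at ", sum(bad), " grid point(s); dropped")
    o <- o[!bad, ]; e <- e[!bad, ]
  }
  structure(data.frame(time = o$time, rs = o$value / e$value,
                       lo = o$lo / e$value, hi = o$hi / e$value,
                       extrapolated = o$extrapolated | e$extrapolated),
            k = attr(expected, "k"), class = c("rel_survival", "data.frame"))
}
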