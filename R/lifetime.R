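#' Raw proportion of deaths due to the cancer
#'
#' `o_cancer / (o_cancer + o_other + n_alive_projected)`: the crude lifetime
#' risk among observed deaths, optionally projecting survivors as future
#' other-cause deaths (which lowers the estimate toward its long-run value).
#'
#' @param o_cancer observed cancer deaths.
#' @param o_other observed other-cause deaths.
#' @param n_alive_projected survivors assumed to eventually die of other
#'   causes.
#' @return A proportion in `[0, 1]`.
#' @export
raw_proportion <- function(o_cancer, o_other, n_alive_projected = 0) {
  stopifnot(o_cancer >= 0, o_other >= 0, n_alive_projected >= 0)
  denom <- o_cancer + o_other + n_alive_projected
  if (denom == 0) stop("raw proportion undefined: zero denominator")
  o_cancer / denom
}

#' Compare five lifetime-risk estimators on one cohort
#'
#' Runs the full pipeline end to end and reports the lifetime risk of death
#' due to the cancer five ways:
#' \describe{
#'   \item{raw proportion}{cancer deaths over all deaths, with and without
#'     projecting survivors as other-cause deaths (uses cause of death).}
#'   \item{1 - MFS}{Kaplan-Meier metastasis-free survival complement, read
#'     at `cod_time` (uses cause of death).}
#'   \item{CIF limit}{Aalen-Johansen cancer-death cumulative incidence at
#'     `cod_time`, flagged as a plateau when the last two grid values differ
#'     by less than 0.005 (uses cause of death).}
#'   \item{1 - RS}{relative survival complement at `plateau_time`; relative
#'     survival divides observed overall survival by the survival of `k`
#'     simulated matched normals per case (ignores cause of death).}
#'   \item{EAR-based}{`1 - exp(-AUC)` of the trigam excess-hazard fit to the
#'     observed/expected tabulation (ignores cause of death).}
#' }
#' The report also carries the full comparison grid of OS, MFS, both
#' cumulative incidence curves, and RS with confidence intervals.
#'
#' @param cohort a [new_cohort()].
#' @param table a [new_lifetable()].
#' @param grid evaluation times in years.
#' @param plateau_time read-off time for `1 - RS` (the relative-survival
#'   plateau), years.
#' @param cod_time read-off time for the cause-of-death based curve limits,
#'   years.
#' @param k_matched simulated normals per case.
#' @param seed integer seed for the matched-cohort simulation and fit starts.
#' @param breaks interval boundaries for [tabulate_ear()].
#' @param n_starts optimisation starts for [fit_trigam()].
#' @param fix_triangle drop the trigam triangle wave (sparse cohorts).
#' @return Object of class `lifetime_report`.
#' @export
compare_estimators <- function(cohort, table, grid = c(5, 10, 15, 20, 25, 30, 35),
                               plateau_time = 25, cod_time = 35,
                               k_matched = 3, seed = 1,
                               breaks = default_breaks(), n_starts = 5,
                               fix_triangle = FALSE) {
  stopifnot(inherits(cohort, "cohort"), nrow(cohort) >= 1)
  run <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", stage, "' failed: ", conditionMessage(e), call. = FALSE))
  }
  d_cancer <- sum(cohort$status == "dead_cancer")
  d_other <- sum(cohort$status == "dead_other")
  n_alive <- sum(cohort$status == "alive")
  raw <- run("raw_proportion", raw_proportion(d_cancer, d_other))
  raw_proj <- run("raw_proportion", raw_proportion(d_cancer, d_other, n_alive))

  os <- run("km_os", { ev <- code_events(cohort, "OS"); km_fit(ev$time, ev$event) })
  mfs <- run("km_mfs", { ev <- code_events(cohort, "MFS"); km_fit(ev$time, ev$event) })
  cause <- ifelse(cohort$status == "dead_cancer", 1L,
                  ifelse(cohort$status == "dead_other", 2L, 0L))
  cif <- run("cif", cif_fit(cohort$futime, cause))

  expc <- run("sim_expected", sim_expected(cohort, table, k = k_matched, seed = seed))
  sexp <- run("expected_survival", expected_survival(expc))
  rs <- run("relative_survival",
            relative_survival(os, sexp, sort(unique(c(grid, plateau_time)))))

  ear <- run("tabulate_ear", tabulate_ear(cohort, table, breaks))
  fit <- run("fit_trigam", fit_trigam(ear, fix_triangle = fix_triangle,
                                      n_starts = n_starts, seed = seed))

  at <- function(curve, t) eval_at(curve, t)
  mfs_t <- at(mfs, cod_time)
  cif_t <- at(cif$cancer, cod_time)
  cif_grid <- at(cif$cancer, grid)
  ng <- nrow(cif_grid)
  plateau_flag <- ng >= 2 &&
    abs(cif_grid$value[ng] - cif_grid$value[ng - 1]) < 0.005
  rs_t <- rs[match(plateau_time, rs$time), ]

  table2 <- data.frame(year = grid,
                       OS = at(os, grid)$value,
                       OS_lo = at(os, grid)$lo, OS_hi = at(os, grid)$hi,
                       MFS = at(mfs, grid)$value,
                       MFS_lo = at(mfs, grid)$lo, MFS_hi = at(mfs, grid)$hi,
                       CIF_other = at(cif$other, grid)$value,
                       CIF_cancer = cif_grid$value,
                       CIF_cancer_lo = cif_grid$lo, CIF_cancer_hi = cif_grid$hi,
                       RS = rs$rs[match(grid, rs$time)],
                       RS_lo = rs$lo[match(grid, rs$time)],
                       RS_hi = rs$hi[match(grid, rs$time)])

  structure(list(
    raw_prop = raw, raw_prop_projected = raw_proj,
    one_minus_mfs = c(est = 1 - mfs_t$value, lo = 1 - mfs_t$hi, hi = 1 - mfs_t$lo),
    cif_limit = c(est = cif_t$value, lo = cif_t$lo, hi = cif_t$hi),
    cif_plateau = plateau_flag,
    one_minus_rs = c(est = 1 - rs_t$rs, lo = 1 - rs_t$hi, hi = 1 - rs_t$lo),
    ear_based = lifetime_risk_from_auc(fit$auc),
    auc = fit$auc,
    uses_cod = c(raw_prop = TRUE, one_minus_mfs = TRUE, cif_limit = TRUE,
                 one_minus_rs = FALSE, ear_based = FALSE),
    plateau_time = plateau_time, cod_time = cod_time, grid = grid,
    table2 = table2, ear_table = ear, trigam_fit = fit,
    curves = list(os = os, mfs = mfs, cif = cif, expected = sexp, rs = rs),
    config = list(k_matched = k_matched, seed = seed, breaks = breaks,
                  n_starts = n_starts, fix_triangle = fix_triangle)),
    class = "lifetime_report")
}

#' @export
print.lifetime_report <- function(x, ...) {
  pct <- function(v) sprintf("%.1f%%", 100 * v)
  cat("Lifetime risk of death due to the cancer, five ways:\n")
  cat(sprintf("  1. raw proportion of deaths        %s (projected: %s)  [uses COD]\n",
              pct(x$raw_prop), pct(x$raw_prop_projected)))
  cat(sprintf("  2. 1 - MFS at %g y                 %s (%s, %s)  [uses COD]\n",
              x$cod_time, pct(x$one_minus_mfs["est"]),
              pct(x$one_minus_mfs["lo"]), pct(x$one_minus_mfs["hi"])))
  cat(sprintf("  3. CIF(cancer) at %g y             %s (%s, %s)%s  [uses COD]\n",
              x$cod_time, pct(x$cif_limit["est"]), pct(x$cif_limit["lo"]),
              pct(x$cif_limit["hi"]),
              if (isTRUE(x$cif_plateau)) " [plateau]" else ""))
  cat(sprintf("  4. 1 - RS at %g y                  %s (%s, %s)  [ignores COD]\n",
              x$plateau_time, pct(x$one_minus_rs["est"]),
              pct(x$one_minus_rs["lo"]), pct(x$one_minus_rs["hi"])))
  cat(sprintf("  5. EAR model 1 - exp(-AUC)         %s (AUC = %.3f)  [ignores COD]\n",
              pct(x$ear_based), x$auc))
  invisible(x)
}
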