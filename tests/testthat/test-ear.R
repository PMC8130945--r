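test_that("default interval schedule widens with follow-up and is overridable", {
  b <- default_breaks()
  expect_equal(b[1:3], c(0, 0.5, 1))
  expect_true(all(diff(diff(b)) >= 0))  # widths nondecreasing
  expect_equal(max(b), 42)

  coh <- one_case(60, 2000, futime = 1.5)
  tab <- tabulate_ear(coh, const_lifetable(0.02), breaks = c(0, 1, 2))
  expect_equal(attr(tab, "breaks"), c(0, 1, 2))
  expect_equal(nrow(tab), 2)
})

test_that("person-year tabulation integrates rates over Lexis cells", {
  # one person, constant m = 0.02, followed one year, alive
  coh <- one_case(60, 2000, futime = 1)
  tab <- tabulate_ear(coh, const_lifetable(0.02), breaks = c(0, 1, 2))
  expect_equal(tab$PY, c(1, 0))
  expect_equal(tab$E[1], 0.02, tolerance = 1e-12)
  expect_equal(tab$O, c(0L, 0L))
  expect_equal(tab$EAR[1], -0.02, tolerance = 1e-12)

  # birthday crossed mid-interval: half a year at 0.02, half at 0.04
  lt_age <- age_lifetable(c("60" = 0.02, "61" = 0.04))
  coh2 <- one_case(60.5, 2000, futime = 1)
  tab2 <- tabulate_ear(coh2, lt_age, breaks = c(0, 1))
  expect_equal(tab2$E, 0.03, tolerance = 1e-12)
  expect_equal(tab2$PY, 1)

  # PY-weighted mean time of a fully-occupied interval is its midpoint
  expect_equal(tab2$t_mid, 0.5)
})

test_that("tabulation conserves person-years and deaths, and matches brute force", {
  lt <- make_synthetic_lifetable()
  coh <- generate_cohort(gen_config(500, seed = 41), lt)
  tab <- tabulate_ear(coh, lt)
  expect_equal(sum(tab$PY), sum(coh$futime), tolerance = 1e-9)
  expect_equal(sum(tab$O), sum(coh$status != "alive"))

  # expected deaths against a daily-grid oracle, case by case
  small <- new_cohort(as.data.frame(coh)[1:20, ], attr(coh, "study_end"))
  tab_s <- tabulate_ear(small, lt, breaks = c(0, 5, 15, 42))
  E_brute <- colSums(t(sapply(seq_len(20), function(i) {
    sapply(1:3, function(j) {
      lo <- min(c(0, 5, 15)[j], small$futime[i])
      hi <- min(c(5, 15, 42)[j], small$futime[i])
      if (hi <= lo) 0 else
        brute_expected(lt, small$sex[i], small$age_dx[i], small$year_dx[i],
                       lo, hi)
    })
  })))
  expect_equal(tab_s$E, E_brute, tolerance = 1e-4)

  # a case beyond the last break is rejected, naming offenders
  expect_error(tabulate_ear(coh, lt, breaks = c(0, 1)),
               "beyond the last break for case")
})

test_that("Garwood intervals and EAR columns are internally consistent", {
  coh <- one_case(60, 2000, futime = 1, status = "dead_other")
  tab <- tabulate_ear(coh, const_lifetable(0.02), breaks = c(0, 2))
  expect_equal(tab$O, 1L)
  # exact Poisson 95% CI for one observed event
  expect_equal(tab$RR_lo * tab$E, qchisq(0.025, 2) / 2, tolerance = 1e-12)
  expect_equal(tab$RR_hi * tab$E, qchisq(0.975, 4) / 2, tolerance = 1e-12)
  expect_equal(tab$EAR, (1 - tab$E) / tab$PY)
  expect_true(tab$EAR_lo <= tab$EAR & tab$EAR <= tab$EAR_hi)
})

test_that("Poisson trigam fit recovers parameters from exact binned data", {
  truth <- trigam_params(A = 0.455, k = 2, theta = 3, H = 0.05, p_c = 3, w = 2)
  breaks <- seq(0, 40, by = 0.5)
  t_mid <- (breaks[-1] + breaks[-length(breaks)]) / 2
  PY <- rep(10000, length(t_mid))
  E <- 0.01 * PY
  O <- round(E + h_trigam(t_mid, truth) * PY)
  tab <- structure(data.frame(t_lo = breaks[-length(breaks)], t_hi = breaks[-1],
                              t_mid = t_mid, PY = PY, O = O, E = E,
                              RR = O / E, RR_lo = NA, RR_hi = NA,
                              EAR = (O - E) / PY, EAR_lo = NA, EAR_hi = NA),
                   breaks = breaks, class = c("ear_table", "data.frame"))
  fit <- fit_trigam(tab, n_starts = 5, seed = 2)
  expect_equal(fit$auc, trigam_auc(truth), tolerance = 0.02)
  expect_equal(fit$convergence, 0)

  # null data: observed equals expected everywhere -> AUC pinned near 0
  tab0 <- tab
  tab0$O <- as.integer(round(E))
  tab0$EAR <- (tab0$O - E) / PY
  fit0 <- fit_trigam(tab0, n_starts = 5, seed = 2)
  expect_lt(fit0$auc, 0.01)

  # triangle can be switched off for sparse cohorts
  fit_nt <- fit_trigam(tab, fix_triangle = TRUE, n_starts = 5, seed = 2)
  expect_equal(fit_nt$params$H, 0)
  expect_equal(fit_nt$auc, fit_nt$params$A)

  # too few populated intervals is an error
  expect_error(fit_trigam(tab[1:4, ]), "at least 6")
})
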