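test_that("Kaplan-Meier matches hand product-limit values on tiny inputs", {
  # no censoring: empirical survival
  f1 <- km_fit(c(1, 2, 3), c(1, 1, 1))
  expect_equal(f1$values, c(2 / 3, 1 / 3, 0), tolerance = 1e-12)

  # censoring at 2: S(1) = 2/3, S(3) = 2/3 * (1 - 1/1) = 0
  f2 <- km_fit(c(1, 2, 3), c(1, 0, 1))
  expect_equal(eval_at(f2, c(1, 3))$value, c(2 / 3, 0), tolerance = 1e-12)

  # all censored: flat at 1, with a warning
  expect_warning(f3 <- km_fit(c(1, 2), c(0, 0)), "censored")
  expect_true(all(f3$values == 1))

  # ties grouped: two deaths at t=1 out of 4
  f4 <- km_fit(c(1, 1, 2, 3), c(1, 1, 1, 0))
  expect_equal(eval_at(f4, c(1, 2))$value, c(1 / 2, 1 / 4), tolerance = 1e-12)
})

test_that("event coding distinguishes OS and MFS", {
  coh <- new_cohort(data.frame(id = c("a", "b", "c"), sex = "female",
                               age_dx = 60, year_dx = 2000,
                               futime = c(5, 5, 12),
                               status = c("dead_other", "dead_cancer", "alive"),
                               morph = 8720L, site = "C69.3"),
                    study_end = 2017)
  os <- code_events(coh, "OS")
  mfs <- code_events(coh, "MFS")
  expect_equal(os$event, c(1L, 1L, 0L))   # other-cause death is an OS event
  expect_equal(mfs$event, c(0L, 1L, 0L))  # ...but censored under MFS
  expect_equal(os$time, c(5, 5, 12))
  expect_equal(mfs$time, os$time)
})

test_that("Aalen-Johansen incidence matches hand-computed values", {
  # two cases, one event of each cause
  ci <- cif_fit(c(1, 2), c(1L, 2L))
  expect_equal(eval_at(ci$cancer, c(1, 2))$value, c(0.5, 0.5))
  expect_equal(eval_at(ci$other, c(1, 2))$value, c(0, 0.5))

  # five cases, hand Aalen-Johansen:
  # t=1 cause1: CIF1 += 1/5;           t=2 cause2: CIF2 += (4/5)(1/4) = 1/5
  # t=3 cause1: CIF1 += (3/5)(1/3) = 1/5;  t=4 censored
  # t=5 cause2: CIF2 += (2/5)(1/1) = 2/5
  ci5 <- cif_fit(c(1, 2, 3, 4, 5), c(1L, 2L, 1L, 0L, 2L))
  expect_equal(eval_at(ci5$cancer, c(1, 3, 5))$value, c(0.2, 0.4, 0.4),
               tolerance = 1e-12)
  expect_equal(eval_at(ci5$other, c(2, 5))$value, c(0.2, 0.6),
               tolerance = 1e-12)

  # single cause, no censoring: competing risks collapse to the KM complement
  set.seed(4)
  tt <- rexp(40)
  ci1 <- suppressWarnings(cif_fit(tt, rep(1L, 40)))
  km <- km_fit(tt, rep(1, 40))
  expect_equal(ci1$cancer$values, 1 - km$values, tolerance = 1e-12)
  expect_equal(max(ci1$cancer$values), 1)
  expect_true(all(ci1$other$values == 0))
})

test_that("cause incidences and all-cause KM conserve probability", {
  lt <- make_synthetic_lifetable()
  for (seed in 1:3) {
    coh <- generate_cohort(gen_config(400, seed = seed), lt)
    cause <- ifelse(coh$status == "dead_cancer", 1L,
                    ifelse(coh$status == "dead_other", 2L, 0L))
    ci <- cif_fit(coh$futime, cause)
    ev <- code_events(coh, "OS")
    km <- km_fit(ev$time, ev$event)
    tg <- sort(unique(coh$futime[cause > 0]))
    total <- eval_at(ci$cancer, tg)$value + eval_at(ci$other, tg)$value +
      eval_at(km, tg)$value
    expect_equal(total, rep(1, length(tg)), tolerance = 1e-9)
  }
})

test_that("MFS dominates OS pointwise on the same cohort", {
  lt <- make_synthetic_lifetable()
  coh <- generate_cohort(gen_config(2000, seed = 8), lt)
  os <- km_fit(code_events(coh, "OS")$time, code_events(coh, "OS")$event)
  mfs <- km_fit(code_events(coh, "MFS")$time, code_events(coh, "MFS")$event)
  grid <- seq(0, 40, by = 1)
  expect_true(all(eval_at(mfs, grid)$value >= eval_at(os, grid)$value - 1e-12))
})

test_that("step curves evaluate right-continuously and flag extrapolation", {
  curve <- new_step_survival(times = c(2, 4), values = c(0.5, 0.25),
                             lo = c(0.4, 0.15), hi = c(0.6, 0.35),
                             kind = "survival")
  ev <- eval_at(curve, c(0, 1.99, 2, 3, 4, 10))
  expect_equal(ev$value, c(1, 1, 0.5, 0.5, 0.25, 0.25))
  expect_equal(ev$extrapolated, c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE))
  expect_equal(ev$lo[3], 0.4)

  inc <- new_step_survival(times = 1, values = 0.3, kind = "incidence")
  expect_equal(eval_at(inc, 0)$value, 0)

  # KM with no censoring equals the empirical survival function
  set.seed(2)
  tt <- round(rexp(30), 2) + 0.01
  km <- km_fit(tt, rep(1, 30))
  for (t in c(0.2, 0.7, 1.5))
    expect_equal(eval_at(km, t)$value, mean(tt > t), tolerance = 1e-12)
})
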