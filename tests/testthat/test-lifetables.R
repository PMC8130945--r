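test_that("rates are piecewise constant on unit Lexis cells and clamp at edges", {
  lt <- make_synthetic_lifetable(makeham_a = 0.05, gompertz_b = 0,
                                 years = 1995:2005, secular_decline = 0,
                                 male_ratio = 1)
  # within-cell constancy: any two points in one cell agree
  expect_identical(get_rate(lt, "male", 80.7, 2000.3),
                   get_rate(lt, "male", 80.0, 2000.0))
  for (p in list(c(80.1, 2000.1), c(80.9, 2000.9), c(80.5, 2000.0))) {
    expect_identical(get_rate(lt, "female", p[1], p[2]),
                     get_rate(lt, "female", 80, 2000))
  }
  # age clamps to the open terminal cell, for all years and sexes
  expect_identical(get_rate(lt, "female", 140, 2010),
                   get_rate(lt, "female", 110, 2010))
  # years clamp to the nearest boundary
  expect_identical(get_rate(lt, "male", 50, 1950), get_rate(lt, "male", 50, 1995))
  expect_identical(get_rate(lt, "male", 50, 2050), get_rate(lt, "male", 50, 2005))
  expect_error(get_rate(lt, "male", -1, 2000), "age")
  expect_error(get_rate(lt, "dog", 50, 2000), "sex")
})

test_that("synthetic Gompertz-Makeham table matches its closed form", {
  a <- 0.001; b <- 2e-5; cc <- 0.095; dec <- 0.01
  lt <- make_synthetic_lifetable(a, b, cc, years = 2000:2020,
                                 secular_decline = dec, male_ratio = 1)
  # closed form evaluated independently of the constructor
  expect_equal(get_rate(lt, "female", 70, 2010),
               (0.001 + 2e-5 * exp(6.65)) * 0.99^10, tolerance = 1e-12)
  expect_equal(get_rate(lt, "female", 60.4, 2000.9),
               a + b * exp(cc * 60), tolerance = 1e-12)

  # spec'd male scaling
  lt2 <- make_synthetic_lifetable(a, b, cc, years = 2000:2010,
                                  secular_decline = 0, male_ratio = 1.3)
  expect_equal(get_rate(lt2, "male", 50, 2005),
               1.3 * get_rate(lt2, "female", 50, 2005))

  # zero parameters give an immortal population
  lt0 <- make_synthetic_lifetable(0, 0, 0.1, years = 2000:2001)
  expect_true(all(lt0$rates == 0))

  # no secular decline: rates identical across years
  ltc <- make_synthetic_lifetable(years = 2000:2010, secular_decline = 0)
  expect_true(all(ltc$rates[, 1, ] == ltc$rates[, 11, ]))

  # monotone nondecreasing in age when a, b >= 0
  for (s in c("female", "male")) {
    r <- get_rate(ltc, s, 0:110, 2005)
    expect_true(all(diff(r) >= 0))
  }

  # explosive parameters are capped at 10 with a warning
  expect_warning(lt_cap <- make_synthetic_lifetable(gompertz_b = 1e-3,
                                                    gompertz_c = 0.15,
                                                    years = 2000:2001),
                 "capped")
  expect_lte(max(lt_cap$rates), 10)
})

test_that("HMD Mx_1x1 reader parses, fills '.' and round-trips", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("United States, Death rates (period 1x1)", "",
               "  Year  Age  Female  Male  Total",
               "  2000  0  0.006  0.007  0.0065",
               "  2000  1  0.0005  0.0006  0.00055",
               "  2000  110+  0.6  0.7  0.65"), f)
  lt <- read_hmd_mx(f)
  expect_equal(lt$year_min, 2000)
  expect_equal(lt$year_max, 2000)
  expect_equal(lt$age_max, 110)
  expect_equal(get_rate(lt, "female", 0, 2000), 0.006)
  expect_equal(get_rate(lt, "male", 0.9, 2000), 0.007)
  expect_equal(get_rate(lt, "female", 110, 2000), 0.6)
  # ages 2..109 were absent from the file and default to 0
  expect_equal(get_rate(lt, "male", 50, 2000), 0)

  # '.' fills with the last finite rate at lower age for that sex/year
  f2 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("Header", "Year Age Female Male Total",
               "2001 0 0.004 0.005 0.0045",
               "2001 1 . 0.0004 0.0004",
               "2001 2 0.0002 0.0003 0.00025"), f2)
  lt2 <- read_hmd_mx(f2)
  expect_equal(get_rate(lt2, "female", 1, 2001), 0.004)
  expect_equal(get_rate(lt2, "male", 1, 2001), 0.0004)

  # round trip: write then reparse reproduces every rate
  lt3 <- make_synthetic_lifetable(years = 2000:2003, ages = 0:110)
  f3 <- withr::local_tempfile(fileext = ".txt")
  write_hmd_mx(lt3, f3)
  lt3b <- read_hmd_mx(f3)
  expect_equal(lt3b$rates, lt3$rates, tolerance = 1e-7)
  expect_equal(lt3b$age_max, lt3$age_max)

  # malformed column count names the offending line
  f4 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("Year Age Female Male Total",
               "2000 0 0.006 0.007 0.0065",
               "2000 1 0.0005 0.0006"), f4)
  expect_error(read_hmd_mx(f4), "line 3")

  # non-monotone ages within a year are rejected
  f5 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("Year Age Female Male Total",
               "2000 1 0.0005 0.0006 0.00055",
               "2000 0 0.006 0.007 0.0065"), f5)
  expect_error(read_hmd_mx(f5), "monotone")
})
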