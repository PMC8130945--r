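#' Background mortality rate surface
#'
#' A `lifetable` holds annual central death rates m(sex, age, year), indexed by
#' single year of age and single calendar year, for two sexes. Rates are used
#' directly as constant hazards within each one-year Lexis cell, so survival
#' over a duration d inside a cell is exp(-m * d). This makes expected-death
#' integration exact and additive over Lexis splits.
#'
#' @param rates numeric array with dim `c(n_age, n_year, 2)`; third dimension
#'   ordered as `sexes`. All entries must be finite and non-negative.
#' @param age_min,age_max integer age bounds (the last age is an open "110+"
#'   style terminal cell: ages above `age_max` clamp to it).
#' @param year_min,year_max integer calendar-year bounds; years outside clamp
#'   to the nearest boundary year.
#' @param sexes character vector of length 2 naming the sex categories.
#' @return An object of class `lifetable`.
#' @export
new_lifetable <- function(rates, age_min, age_max, year_min, year_max,
                          sexes = c("female", "male")) {
  stopifnot(is.array(rates), length(dim(rates)) == 3L, length(sexes) == 2L)
  n_age <- age_max - age_min + 1L
  n_year <- year_max - year_min + 1L
  if (!identical(dim(rates), c(n_age, n_year, 2L)))
    stop("rates array must have dim c(", n_age, ", ", n_year, ", 2)")
  if (anyNA(rates) || any(!is.finite(rates)) || any(rates < 0))
    stop("all life-table rates must be finite and >= 0")
  dimnames(rates) <- list(age_min:age_max, year_min:year_max, sexes)
  structure(list(rates = rates,
                 age_min = as.integer(age_min), age_max = as.integer(age_max),
                 year_min = as.integer(year_min), year_max = as.integer(year_max),
                 sexes = sexes),
            class = "lifetable")
}

#' @export
print.lifetable <- function(x, ...) {
  cat("Life table: ages ", x$age_min, "-", x$age_max,
      " (terminal cell open), years ", x$year_min, "-", x$year_max,
      ", sexes ", paste(x$sexes, collapse = "/"), "\n", sep = "")
  cat("  rate range: [", format(min(x$rates)), ", ", format(max(x$rates)), "] per person-year\n",
      sep = "")
  invisible(x)
}

#' Look up a background mortality rate
#'
#' Returns the rate of the Lexis cell containing (sex, floor(age),
#' floor(year)). The rate is piecewise constant on unit age x year cells.
#' Ages above `age_max` clamp to the terminal cell; calendar years outside
#' the table clamp to the nearest boundary year (so follow-up past the last
#' table year remains computable).
#'
#' All of `sex`, `age`, `year` are vectorised and recycled to a common length.
#'
#' @param table a [new_lifetable()] object.
#' @param sex character vector of sex labels (must match `table$sexes`).
#' @param age numeric vector of ages in years, `>= 0`.
#' @param year numeric vector of calendar years.
#' @return numeric vector of hazards per person-year.
#' @export
get_rate <- function(table, sex, age, year) {
  stopifnot(inherits(table, "lifetable"))
  n <- max(length(sex), length(age), length(year))
  sex <- rep_len(sex, n); age <- rep_len(age, n); year <- rep_len(year, n)
  if (any(age < 0)) stop("age must be >= 0")
  si <- match(sex, table$sexes)
  if (anyNA(si)) stop("unknown sex label: ", paste(unique(sex[is.na(si)]), collapse = ", "))
  ai <- pmin(floor(age), table$age_max)
  if (any(ai < table$age_min)) stop("age below table age_min (", table$age_min, ")")
  ai <- ai - table$age_min + 1
  yi <- pmin(pmax(floor(year), table$year_min), table$year_max) - table$year_min + 1
  table$rates[cbind(ai, yi, si)]
}

#' Synthetic Gompertz-Makeham life table
#'
#' Builds a period life table with rate
#' `(a + b * exp(c * age)) * (1 - secular_decline)^(year - year_min)`,
#' optionally scaled for males by a fixed male:female ratio. This emulates the
#' age structure and secular improvement of national mortality surfaces and
#' stands in for registry-linked national life tables in simulation studies.
#'
#' Defaults give an adult mortality curve of realistic magnitude (about
#' 0.009/y at 63, 0.06/y at 85) with a 1%/year secular decline and 20% male
#' excess. Rates above 10 per person-year are capped with a warning.
#'
#' @param makeham_a age-independent (Makeham) hazard component, `>= 0`.
#' @param gompertz_b Gompertz amplitude, `>= 0`.
#' @param gompertz_c Gompertz slope per year of age, `> 0`.
#' @param years integer vector of calendar years covered.
#' @param ages integer vector of ages covered (terminal age open-ended).
#' @param secular_decline fractional decline of all rates per calendar year,
#'   in `[0, 1)`.
#' @param male_ratio multiplicative male:female rate ratio.
#' @return A [new_lifetable()] object.
#' @export
make_synthetic_lifetable <- function(makeham_a = 5e-4, gompertz_b = 3e-5,
                                     gompertz_c = 0.09,
                                     years = 1970:2020, ages = 0:110,
                                     secular_decline = 0.01, male_ratio = 1.2) {
  stopifnot(makeham_a >= 0, gompertz_b >= 0, gompertz_c > 0,
            secular_decline >= 0, secular_decline < 1, male_ratio > 0)
  ages <- sort(as.integer(ages)); years <- sort(as.integer(years))
  base <- makeham_a + gompertz_b * exp(gompertz_c * ages)
  decay <- (1 - secular_decline)^(years - years[1])
  f <- outer(base, decay)
  rates <- array(c(f, f * male_ratio), dim = c(length(ages), length(years), 2L))
  if (any(rates > 10)) {
    warning("life-table rates above 10 per person-year capped at 10")
    rates[rates > 10] <- 10
  }
  new_lifetable(rates, min(ages), max(ages), min(years), max(years))
}
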