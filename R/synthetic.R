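#' Synthetic-registry generator configuration
#'
#' Defines the statistical structure a registry analysis assumes: age/sex/
#' year-of-diagnosis demographics, a background mortality surface (supplied
#' separately as a life table), an injected trigam excess hazard, optional
#' misreporting of cancer deaths as other-cause deaths, and administrative
#' censoring at a study end date.
#'
#' Defaults emulate a US uveal-melanoma registry cohort: age at diagnosis
#' normal(63, 13) truncated to [3, 99], 52.3% male, diagnoses uniform over
#' 1975 through end of 2016 with follow-up administratively censored at the
#' end of 2016 (`study_end = 2017`), and a trigam excess hazard with
#' AUC 0.555.
#'
#' @param n_cases number of cases to generate, `>= 1`.
#' @param seed integer RNG seed; the generated cohort is fully reproducible
#'   from it.
#' @param age_mean,age_sd,age_range truncated-normal age-at-diagnosis
#'   distribution (a degenerate `age_range` pins the age).
#' @param sex_ratio fraction male.
#' @param dx_year_range real calendar interval of diagnosis dates (uniform).
#' @param trigam a [trigam_params()] object: the true injected excess hazard.
#' @param misreport_frac probability that a cancer death is relabelled
#'   `dead_other`, in `[0, 1]`.
#' @param study_end real calendar year of administrative censoring.
#' @return An object of class `gen_config`.
#' @export
gen_config <- function(n_cases, seed = 1, age_mean = 63, age_sd = 13,
                       age_range = c(3, 99), sex_ratio = 0.523,
                       dx_year_range = c(1975, 2017),
                       trigam = trigam_params(), misreport_frac = 0,
                       study_end = 2017) {
  stopifnot(n_cases >= 1, misreport_frac >= 0, misreport_frac <= 1,
            inherits(trigam, "trigam_params"), age_range[1] >= 0,
            sex_ratio >= 0, sex_ratio <= 1,
            study_end > dx_year_range[1])
  structure(list(n_cases = as.integer(n_cases), seed = as.integer(seed),
                 age_mean = age_mean, age_sd = age_sd, age_range = age_range,
                 sex_ratio = sex_ratio, dx_year_range = dx_year_range,
                 trigam = trigam, misreport_frac = misreport_frac,
                 study_end = study_end),
            class = "gen_config")
}

# truncated-normal sampler by rejection; degenerate range pins the value
.rtruncnorm <- function(n, mean, sd, range) {
  if (diff(range) <= 0) return(rep(range[1], n))
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(n, mean, sd)
    out <- c(out, x[x >= range[1] & x <= range[2]])
  }
  out[seq_len(n)]
}

#' Generate a synthetic registry cohort with known excess hazard
#'
#' Each case's time to death is simulated under the total hazard
#' `lambda(t) = m(sex, age_dx + t, year_dx + t) + h_trigam(t)`: follow-up is
#' split into segments at every integer age and calendar-year boundary and at
#' the trigam breakpoints; within a segment the background rate is the Lexis
#' cell constant and the trigam component enters through its exact segment
#' average (difference of the closed-form cumulative hazard), so the
#' piecewise-constant process matches the continuous cumulative excess hazard
#' exactly at all segment boundaries. The death time is drawn by inversion of
#' the cumulative hazard against a unit exponential; the component firing at
#' that time assigns `dead_other` (background) vs `dead_cancer` (excess) by
#' competing-exponentials odds. Deaths after `study_end - year_dx` are
#' censored `alive`; simulants reaching age 120 die of other causes at the
#' cap. Finally each cancer death is relabelled `dead_other` with probability
#' `misreport_frac`, emulating cause-of-death under-reporting.
#'
#' @param cfg a [gen_config()].
#' @param table a [new_lifetable()] covering the cohort's diagnosis years
#'   (later years clamp) and ages up to the table's terminal age.
#' @return A [new_cohort()] with ICD-O-3 melanoma morphology and uveal site
#'   codes attached.
#' @export
generate_cohort <- function(cfg, table) {
  stopifnot(inherits(cfg, "gen_config"), inherits(table, "lifetable"))
  if (cfg$dx_year_range[1] < table$year_min)
    stop("life table does not cover the start of dx_year_range")
  if (cfg$age_range[2] > table$age_max + 1)
    stop("life table does not cover the diagnosis age range")
  set.seed(cfg$seed)
  n <- cfg$n_cases
  sex <- ifelse(stats::runif(n) < cfg$sex_ratio, "male", "female")
  # registries report age at diagnosis in completed years
  age_dx <- floor(.rtruncnorm(n, cfg$age_mean, cfg$age_sd, cfg$age_range))
  year_dx <- stats::runif(n, cfg$dx_year_range[1], cfg$dx_year_range[2])
  morph <- sample(c(8720L, 8721L, 8770L, 8772L, 8773L), n, replace = TRUE,
                  prob = c(0.6, 0.1, 0.15, 0.1, 0.05))
  site <- sample(c("C69.2", "C69.3", "C69.4"), n, replace = TRUE,
                 prob = c(0.05, 0.86, 0.09))
  e <- stats::rexp(n)

  t_cens <- cfg$study_end - year_dx
  if (any(t_cens <= 0)) stop("study_end precedes some diagnosis dates")
  t_stop <- pmin(t_cens, 120 - age_dx)

  tg <- cfg$trigam
  extra <- sort(unique(pmax(0, c(tg$p_c - tg$w, tg$p_c, tg$p_c + tg$w))))
  seg <- .lexis_segments(t_stop, age_dx, year_dx, extra)
  i <- seg$case
  wdt <- seg$t_hi - seg$t_lo
  mid <- (seg$t_lo + seg$t_hi) / 2
  m <- get_rate(table, sex[i], age_dx[i] + mid, year_dx[i] + mid)
  hbar <- (trigam_cumhaz(seg$t_hi, tg) - trigam_cumhaz(seg$t_lo, tg)) / wdt
  lam <- m + hbar
  dL <- lam * wdt

  cl <- cumsum(dL)
  nseg <- length(i)
  last_row <- which(c(i[-1] != i[-nseg], TRUE))
  offset_case <- c(0, cl[last_row[-length(last_row)]])
  Lam <- cl - offset_case[i]

  hit <- Lam >= e[i]
  sel <- which(hit)
  firsts <- sel[!duplicated(i[sel])]
  died <- i[firsts]
  t_death <- seg$t_lo[firsts] + (e[died] - (Lam[firsts] - dL[firsts])) / lam[firsts]
  p_cancer <- hbar[firsts] / lam[firsts]
  cancer <- stats::runif(length(firsts)) < p_cancer

  futime <- t_stop
  status <- rep("alive", n)
  futime[died] <- t_death
  status[died] <- ifelse(cancer, "dead_cancer", "dead_other")
  capped <- setdiff(which(t_stop < t_cens - 1e-9), died)
  status[capped] <- "dead_other"  # reached the age cap before study end

  mc <- which(status == "dead_cancer")
  if (cfg$misreport_frac > 0 && length(mc)) {
    flip <- stats::runif(length(mc)) < cfg$misreport_frac
    status[mc[flip]] <- "dead_other"
  }

  new_cohort(data.frame(id = sprintf("case%06d", seq_len(n)), sex = sex,
                        age_dx = age_dx, year_dx = year_dx, futime = futime,
                        status = status, morph = morph, site = site,
                        stringsAsFactors = FALSE),
             study_end = cfg$study_end)
}
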