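#' Survival / incidence step function
#'
#' Container for a right-continuous step estimate: event times (strictly
#' increasing), estimate values in `[0, 1]`, pointwise 95% confidence bounds,
#' and at-risk/event counts. `kind = "survival"` curves start at 1 and are
#' nonincreasing; `kind = "incidence"` curves start at 0 and are
#' nondecreasing.
#'
#' @param times strictly increasing event times in years.
#' @param values estimate at each time.
#' @param lo,hi pointwise confidence bounds (`NA` allowed, e.g. simulated
#'   expected-survival curves carry no analytic CI).
#' @param n_risk,n_event at-risk and event counts at each time.
#' @param kind `"survival"` or `"incidence"`.
#' @param conf_level nominal confidence level of `lo`/`hi`.
#' @return An object of class `step_survival`.
#' @export
new_step_survival <- function(times, values, lo = NULL, hi = NULL,
                              n_risk = NULL, n_event = NULL,
                              kind = c("survival", "incidence"),
                              conf_level = 0.95) {
  kind <- match.arg(kind)
  k <- length(times)
  if (is.null(lo)) lo <- rep(NA_real_, k)
  if (is.null(hi)) hi <- rep(NA_real_, k)
  if (is.null(n_risk)) n_risk <- rep(NA_integer_, k)
  if (is.null(n_event)) n_event <- rep(NA_integer_, k)
  stopifnot(length(values) == k, length(lo) == k, length(hi) == k,
            !is.unsorted(times, strictly = TRUE),
            all(values >= -1e-12 & values <= 1 + 1e-12))
  if (kind == "survival" && is.unsorted(rev(values)))
    stop("survival values must be nonincreasing")
  if (kind == "incidence" && is.unsorted(values))
    stop("incidence values must be nondecreasing")
  ok <- !is.na(lo) & !is.na(hi)
  if (any(lo[ok] > values[ok] + 1e-8) || any(hi[ok] < values[ok] - 1e-8))
    stop("confidence bounds must bracket the estimate")
  structure(list(times = times, values = values, lo = lo, hi = hi,
                 n_risk = n_risk, n_event = n_event, kind = kind,
                 conf_level = conf_level),
            class = "step_survival")
}

#' @export
print.step_survival <- function(x, ...) {
  cat("Step ", x$kind, " estimate: ", length(x$times), " times over [",
      format(min(x$times)), ", ", format(max(x$times)), "] years; final value ",
      round(x$values[length(x$values)], 4), "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.step_survival <- function(x, ...) {
  data.frame(time = x$times, estimate = x$values, lo = x$lo, hi = x$hi,
             n_risk = x$n_risk, n_event = x$n_event)
}

#' Code cohort outcomes for a survival metric
#'
#' `OS` (overall survival): any death is an event. `MFS` (metastasis-free
#' survival): only cancer deaths are events — time to metastasis is proxied
#' by time of death due to the cancer, and other-cause deaths are treated as
#' right-censored. Durations are `futime` in both codings.
#'
#' @param cohort a [new_cohort()].
#' @param metric `"OS"` or `"MFS"`.
#' @return List with `time` (durations, years) and `event` (0/1 indicators).
#' @export
code_events <- function(cohort, metric = c("OS", "MFS")) {
  metric <- match.arg(metric)
  event <- if (metric == "OS") as.integer(cohort$status != "alive")
           else as.integer(cohort$status == "dead_cancer")
  list(time = cohort$futime, event = event)
}

#' Kaplan-Meier product-limit estimate
#'
#' Fits `S(t) = prod_{t_i <= t} (1 - d_i / n_i)` with ties grouped, Greenwood
#' variance, and 95% confidence intervals on the log(-log S) scale (so the
#' bounds stay in `[0, 1]`). Deaths precede censorings at identical times.
#' Computation is delegated to [survival::survfit()].
#'
#' @param times durations in years, `> 0`.
#' @param events 0/1 event indicators.
#' @param conf_level confidence level.
#' @return A [new_step_survival()] of kind `"survival"`.
#' @export
km_fit <- function(times, events, conf_level = 0.95) {
  stopifnot(length(times) == length(events), length(times) >= 1,
            all(times > 0), all(events %in% c(0, 1)))
  if (all(events == 0))
    warning("all observations censored: survival estimate is flat at 1")
  fit <- survival::survfit(survival::Surv(times, events) ~ 1,
                           conf.type = "log-log", conf.int = conf_level)
  lo <- fit$lower; hi <- fit$upper
  # log-log CI degenerates at S = 0 or S = 1; pin bounds to the estimate
  lo[is.na(lo)] <- fit$surv[is.na(lo)]
  hi[is.na(hi)] <- fit$surv[is.na(hi)]
  new_step_survival(fit$time, fit$surv, lo, hi, fit$n.risk, fit$n.event,
                    kind = "survival", conf_level = conf_level)
}

#' Aalen-Johansen cumulative incidence of competing causes
#'
#' Estimates `CIF_k(t) = sum_{t_i <= t} S(t_i-) d_{k,i} / n_i` for cause 1
#' (cancer) and cause 2 (other), where `S` is the all-cause Kaplan-Meier.
#' Estimation and the counting-process variance are delegated to
#' [cmprsk::cuminc()]; 95% confidence intervals are formed on the
#' `log(-log(1 - CIF))` scale. A cause with no events yields a curve
#' identically 0, with a warning.
#'
#' @param times durations in years, `> 0`.
#' @param cause integer per case: 0 = censored, 1 = cancer death,
#'   2 = other-cause death.
#' @param conf_level confidence level.
#' @return Named list `cancer`/`other` of [new_step_survival()] objects of
#'   kind `"incidence"`.
#' @export
cif_fit <- function(times, cause, conf_level = 0.95) {
  stopifnot(all(cause %in% 0:2), all(times > 0))
  if (!any(cause > 0)) stop("at least one event of some cause is required")
  ci <- cmprsk::cuminc(times, cause, cencode = 0)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  event_times <- sort(unique(times[cause > 0]))
  one_cause <- function(code) {
    comp <- ci[[paste("1", code)]]
    if (is.null(comp)) {
      warning("no events of cause ", code, ": incidence curve is 0")
      return(new_step_survival(event_times, rep(0, length(event_times)),
                               rep(0, length(event_times)), rep(0, length(event_times)),
                               kind = "incidence", conf_level = conf_level))
    }
    # cuminc returns a plotting grid with duplicated times; take the value
    # attained at (right-continuous) each distinct event time
    idx <- findInterval(event_times, comp$time)
    est <- comp$est[idx]
    v <- comp$var[idx]
    se <- sqrt(pmax(v, 0))
    lo <- est; hi <- est
    pos <- est > 0 & est < 1 & se > 0
    lg <- log(-log(1 - est[pos]))
    sl <- se[pos] / ((1 - est[pos]) * abs(log(1 - est[pos])))
    lo[pos] <- 1 - exp(-exp(lg - z * sl))
    hi[pos] <- 1 - exp(-exp(lg + z * sl))
    est <- cummax(est)  # guard monotonicity against representation noise
    new_step_survival(event_times, est, pmin(lo, est), pmax(hi, est),
                      kind = "incidence", conf_level = conf_level)
  }
  list(cancer = one_cause(1), other = one_cause(2))
}

#' Evaluate a step curve on a time grid
#'
#' Right-continuous step interpolation: the value attained at the last event
#' time `<= t`. Before the first event time a survival curve is 1 and an
#' incidence curve is 0. Times beyond the last event time return the last
#' value, flagged `extrapolated`.
#'
#' @param curve a [new_step_survival()].
#' @param t_grid nonnegative evaluation times in years.
#' @return Data frame with `time`, `value`, `lo`, `hi`, `extrapolated`.
#' @export
eval_at <- function(curve, t_grid) {
  stopifnot(inherits(curve, "step_survival"), all(t_grid >= 0))
  start <- if (curve$kind == "survival") 1 else 0
  idx <- findInterval(t_grid, curve$times)
  pick <- function(v) c(start, v)[idx + 1]
  data.frame(time = t_grid,
             value = pick(curve$values),
             lo = pick(curve$lo),
             hi = pick(curve$hi),
             extrapolated = t_grid > curve$times[length(curve$times)])
}
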