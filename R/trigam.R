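#' Trigam excess-hazard parameters
#'
#' The trigam model describes the excess death hazard after a cancer
#' diagnosis as the sum of a gamma-density wave and a triangle wave:
#' \deqn{h(t) = A \, \frac{t^{k-1} e^{-t/\theta}}{\Gamma(k)\,\theta^k}
#'       + H \max(0,\, 1 - |t - p_c| / w).}
#' The gamma wave carries the broad early excess; the triangle wave captures
#' a localised bump of force of mortality. Because the gamma factor is a unit
#' area density, `A` is the expected lifetime excess deaths per person
#' contributed by the wave, and the total area under the curve has the closed
#' form `A + H * w` (reduced by the part of the triangle that would fall at
#' negative times when `p_c < w`). Lifetime risk of death due to the cancer
#' is `1 - exp(-AUC)`.
#'
#' @param A gamma-wave amplitude, expected excess deaths per person, `>= 0`.
#' @param k gamma shape, `> 0`.
#' @param theta gamma scale in years, `> 0`.
#' @param H triangle peak height, per person-year, `>= 0`.
#' @param p_c triangle peak location in years since diagnosis, `>= 0`.
#' @param w triangle half-width in years, `> 0`.
#' @return An object of class `trigam_params`.
#' @export
trigam_params <- function(A = 0.455, k = 2, theta = 3, H = 0.05, p_c = 3, w = 2) {
  stopifnot(A >= 0, H >= 0, k > 0, theta > 0, w > 0, p_c >= 0)
  structure(list(A = unname(A), k = unname(k), theta = unname(theta),
                 H = unname(H), p_c = unname(p_c), w = unname(w)),
            class = "trigam_params")
}

#' @export
print.trigam_params <- function(x, ...) {
  cat(sprintf("Trigam excess hazard: gamma wave A=%.4g (k=%.3g, theta=%.3g y)",
              x$A, x$k, x$theta),
      sprintf("+ triangle H=%.4g /y at p_c=%.3g y (half-width %.3g y)", x$H, x$p_c, x$w),
      sprintf("AUC = %.4g excess deaths/person; lifetime risk = %.3g",
              trigam_auc(x), 1 - exp(-trigam_auc(x))), sep = "\n")
  invisible(x)
}

#' Evaluate the trigam excess hazard
#'
#' @param t numeric vector, years since diagnosis, `>= 0`.
#' @param params a [trigam_params()] object.
#' @return Hazard per person-year at each `t`.
#' @export
h_trigam <- function(t, params) {
  stopifnot(inherits(params, "trigam_params"))
  if (any(t < 0)) stop("t must be >= 0")
  params$A * stats::dgamma(t, shape = params$k, scale = params$theta) +
    params$H * pmax(0, 1 - abs(t - params$p_c) / params$w)
}

# antiderivative of the untruncated triangle wave, zero at its left foot
.tri_antideriv <- function(t, H, p_c, w) {
  l <- p_c - w; r <- p_c + w
  ifelse(t <= l, 0,
         ifelse(t <= p_c, H * (t - l)^2 / (2 * w),
                ifelse(t <= r, H * w - H * (r - t)^2 / (2 * w), H * w)))
}

#' Cumulative trigam excess hazard
#'
#' Closed-form integral of [h_trigam()] over `[0, t]` (triangle truncated at
#' `t = 0`).
#'
#' @inheritParams h_trigam
#' @return Cumulative excess hazard (dimensionless) at each `t`.
#' @export
trigam_cumhaz <- function(t, params) {
  stopifnot(inherits(params, "trigam_params"))
  if (any(t < 0)) stop("t must be >= 0")
  with(params,
       A * stats::pgamma(t, shape = k, scale = theta) +
         .tri_antideriv(t, H, p_c, w) - .tri_antideriv(0, H, p_c, w))
}

#' Area under the trigam excess hazard
#'
#' `AUC = A + ` triangle area over `t >= 0`: `H * w` when the whole triangle
#' sits at nonnegative times, `H * w - H * (w - p_c)^2 / (2w)` when `p_c < w`.
#'
#' @param params a [trigam_params()] object.
#' @return Expected lifetime excess deaths per person.
#' @export
trigam_auc <- function(params) {
  with(params, A + H * w - .tri_antideriv(0, H, p_c, w))
}

#' Convert an excess-hazard AUC to lifetime risk
#'
#' The area under the excess hazard is the expected lifetime excess deaths
#' per person; under the additive-excess model the probability of ever dying
#' of the cancer is `1 - exp(-auc)` and the corresponding survival
#' probability is `exp(-auc)` ([survival_from_auc()]).
#'
#' @param auc expected lifetime excess deaths per person, `>= 0`.
#' @return Lifetime probability of death due to the cancer.
#' @export
lifetime_risk_from_auc <- function(auc) {
  if (any(auc < 0)) stop("auc must be >= 0")
  1 - exp(-auc)
}

#' @rdname lifetime_risk_from_auc
#' @return `survival_from_auc()`: the companion survival probability
#'   `exp(-auc)`.
#' @export
survival_from_auc <- function(auc) {
  if (any(auc < 0)) stop("auc must be >= 0")
  exp(-auc)
}
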