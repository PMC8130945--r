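---
title: "Estimating lifetime risk of cancer death five ways"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating lifetime risk of cancer death five ways}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(excessrisk)
```

## The problem

For a cancer such as uveal melanoma — diagnosed at a median age around 63,
with metastatic deaths concentrated in the first decade but continuing at low
rates for decades — the question "what fraction of patients will ever die of
this disease?" has no single obvious estimator. Registry follow-up is long
but thins badly past 15 years; more than half of all deaths are from other
causes; and the cause-of-death (COD) field that several standard estimators
rely on is known to under-report metastatic deaths. `excessrisk` implements
five estimators of this lifetime risk side by side, three of which use COD
labels and two of which deliberately do not:

1. **Raw proportion**: cancer deaths over all deaths, optionally projecting
   current survivors as eventual other-cause deaths.
2. **1 − MFS**: the complement of Kaplan–Meier "metastasis-free survival",
   where time to metastasis is proxied by time of death due to the cancer and
   other-cause deaths are censored.
3. **Cumulative incidence**: the Aalen–Johansen estimator treating cancer
   and other-cause death as competing events.
4. **1 − RS**: relative survival — observed all-cause survival divided by the
   survival of a simulated age/sex/calendar-year matched disease-free
   cohort — read off on its late plateau.
5. **EAR model**: a parametric excess-hazard fit whose area under the curve
   (AUC) converts to lifetime risk as $1 - e^{-\mathrm{AUC}}$.

Estimators 4 and 5 need only all-cause deaths and background life tables, so
the spread between the two groups measures what COD misclassification costs.

## The excess-hazard ("trigam") model

After diagnosis, a patient's death hazard is modelled as background plus
excess:
$$\lambda(t) = m(\mathrm{sex},\, a_0 + t,\, y_0 + t) + h(t),$$
where $m$ is the national mortality rate surface indexed by sex, single year
of age, and calendar year, and $h(t)$ is the disease's excess hazard at time
$t$ since diagnosis. The trigam form is a gamma-density wave plus a triangle
wave:
$$h(t) = A\,\frac{t^{k-1} e^{-t/\theta}}{\Gamma(k)\,\theta^{k}}
        + H \max\!\left(0,\, 1 - \frac{|t - p_c|}{w}\right).$$

The gamma factor is a unit-area density, so $A$ is directly the expected
lifetime excess deaths per person carried by the wave, and
$\mathrm{AUC} = A + Hw$ in closed form (minus the part of the triangle that
would fall at negative times when $p_c < w$; the triangle is truncated at
$t = 0$). Under the additive model the probability of never dying of the
disease is $e^{-\mathrm{AUC}}$.

Default parameters — $A = 0.455$, $k = 2$, $\theta = 3$ y, $H = 0.05$/y,
$p_c = 3$ y, $w = 2$ y, AUC $= 0.555$ — describe an excess hazard peaking
near 0.06–0.1/y around year 3 and essentially gone by year 20, the shape
reported for uveal melanoma; the exact published algebra exists only in
figure form, so these canonical forms are this package's parameterisation.

The model is fit by Poisson regression on binned data: per interval $i$,
observed all-cause deaths $O_i$ have mean
$\lambda_i = E_i + h(t_{\mathrm{mid},i})\,\mathrm{PY}_i$, where $E_i$ is the
expected background deaths and $\mathrm{PY}_i$ the person-years, both
accumulated exactly over unit Lexis cells (see below). We maximise
$\sum_i O_i \log \lambda_i - \lambda_i$ with box-constrained nonnegative
parameters by multi-start L-BFGS-B (5 starts by default, jittered around a
data-driven initialisation, reproducible from a seed), flooring $\lambda_i$
at $10^{-10}$. The midpoint approximation $h(t_\mathrm{mid})$ with
PY-weighted $t_\mathrm{mid}$ follows Poisson-regression-on-bins practice;
its error shrinks with bin width and is covered by the package's 2% recovery
tolerance on dense bins. The nonnegativity constraint means the model cannot
represent the (statistically null) slightly negative late-time EARs real
cohorts show; their confidence intervals include 0.

### Binning

Default intervals are $\{0, 0.5, 1, 2, \ldots, 10, 12, \ldots, 20, 25, 30,
35, 42\}$ years: widths increase with follow-up time so that late, thinned
intervals still accumulate enough deaths for stable rates. The schedule is a
package default (the source analyses do not publish theirs) and is fully
overridable; it is recorded in the output's `breaks` attribute.

## Lexis tabulation and life tables

Rates are annual central death rates used directly as constant hazards
within each one-year age × calendar-year Lexis cell, so within-cell survival
over duration $d$ is $e^{-md}$ and expected deaths integrate exactly and
additively over cell crossings: each case's follow-up is split at every
integer age and calendar-year boundary, and $E$ accrues as
$\sum m \cdot \mathrm{duration}$. Ages above the terminal cell (110+) clamp
to it; calendar years outside the table clamp to the nearest boundary year
so that 40-year follow-ups past the last table year remain computable —
a deliberate choice where the source tooling's behaviour is unstated.
Per-interval uncertainty uses exact Poisson (Garwood) intervals on $O$ with
$E$ fixed, because late bins are small; these are conservative (coverage at
or above nominal).

Life tables come from `read_hmd_mx()` (the Human Mortality Database Mx_1x1
text dialect, with `"110+"` and `"."` handling) or from
`make_synthetic_lifetable()`, a Gompertz–Makeham surface
$(a + be^{c\,\mathrm{age}})(1-\delta)^{\mathrm{year}-\mathrm{year}_0}$ with
defaults $a = 5\times10^{-4}$, $b = 3\times10^{-5}$, $c = 0.09$,
$\delta = 0.01$/y and a 1.2 male:female ratio — adult rates of realistic
magnitude (about 0.009/y at 63, 0.06/y at 85) with a plausible secular
decline.

## Relative survival by matched-cohort simulation

The expected-survival denominator simulates `k = 3` disease-free
counterparts per case, starting from the case's sex, age and year of
diagnosis and stepping one year at a time with the rate refreshed each step;
deaths within a step land uniformly within the year. This yearly-step scheme
is reproduced deliberately — it is how registry relative-survival
denominators are simulated in practice — rather than replaced by exact
piecewise-constant-hazard inversion; at integer times its survival equals
the exact cell-wise product, and its small within-year discretisation bias
is bounded in the test suite. Confidence bounds on RS divide the observed
Kaplan–Meier bounds by the (high-`k`, near-deterministic) expected curve;
the simulation error is not propagated. The plateau read-off time (default
25 y) is a fixed configurable choice rather than automated plateau
detection, matching how the curve is read in practice; the report records
the CIF at a separate read-off (default 35 y) with a plateau flag when the
last two grid values differ by less than 0.005.

## What the synthetic generator emulates — and what it does not

`generate_cohort()` draws demographics (completed-years age at diagnosis
from a truncated normal(63, 13) on [3, 99]; 52.3% male; diagnosis dates
uniform over 1975–2016 with administrative censoring at the end of 2016) and
simulates each death time under the additive hazard above. Follow-up is
split at unit age/year boundaries and at the trigam breakpoints; within a
segment the background rate is the Lexis-cell constant and the trigam
component enters through its exact segment average, so the piecewise process
reproduces the continuous cumulative excess hazard exactly at all segment
boundaries and closed-form oracles (e.g. cure fraction $e^{-\mathrm{AUC}}$
under zero background) hold exactly. Sampling is by inversion against a unit
exponential; cause assignment is by competing-exponential odds within the
firing segment. A `misreport_frac` relabels that fraction of cancer deaths
as other-cause, emulating registry COD under-reporting: it depresses the
three COD-based estimators while leaving RS and EAR unchanged — the central
methodological point the estimator comparison is designed to show.

Ages are emitted in completed years because that is the registry convention
and the convention the yearly-step matched simulation assumes; with
fractional ages the matched arm would systematically sit half a Lexis cell
young.

The generator does not emulate: registry expansion waves (diagnosis dates
are uniform, not weighted by the 9→13→18 registry growth), tumour size or
stage covariates, non-administrative loss to follow-up, or reporting delay.
Consequently, passing parameter-recovery tests shows the estimators are
correct for the assumed statistical structure — additive excess hazard,
accurate life tables, administrative censoring — not that real registry
estimates are free of the biases those omitted features cause. One such
effect is visible even inside the model: administrative censoring time
correlates with calendar-period mortality through the secular decline, so
late-time at-risk sets are enriched for early-diagnosis (higher-mortality)
patients and null-cohort relative survival drifts a few percent below 1 by
30 years. This dependent-censoring effect is intrinsic to the
simulated-expected (Ederer-I-like) approach; at the study sizes used here it
stays within Monte-Carlo bands.

## Numerical choices and edge cases

* Zero recorded survival times become half a month (0.5/12 y) on import:
  registries record whole months and zero-length follow-up breaks
  product-limit estimators. Flagged and logged.
* Kaplan–Meier and CIF confidence intervals are on the log(−log) scale so
  bounds stay in [0, 1]; degenerate endpoints (estimate 0 or 1) pin the
  bounds to the estimate. Deaths precede censorings at tied times.
* Evaluation of step curves is right-continuous; points beyond the last
  event time return the last value flagged `extrapolated` (the 35-year
  column sits near the data's edge).
* The matched simulation forces death at an age cap of 120 (negligible
  mass; guarantees termination); the cohort generator likewise caps.
* `fit_trigam(fix_triangle = TRUE)` drops the triangle wave for sparse or
  young cohorts in which the bump is not statistically detectable.
* Age-group comparisons split at a diagnosis age of 50, with the boundary
  case in the older group.

## Problem sizes

The packaged simulation studies use cohorts of 3,000–20,000 cases (20,000
for parameter recovery and misreporting-ordering checks, 200 replicates of
400 for null-coverage calibration, 50,000 draws for the closed-form cure
fraction), with `k = 3` matched simulants per case — sizes at which
Monte-Carlo error is well below the effects being demonstrated.

## A worked run

```{r example, eval = FALSE}
lt <- make_synthetic_lifetable()
cohort <- generate_cohort(gen_config(n_cases = 10000, seed = 42), lt)
report <- compare_estimators(cohort, lt, seed = 42)
report
```

With the default injected AUC of 0.555 the true lifetime risk is
`1 - exp(-0.555)` = 42.6%; the COD-based and COD-free estimators should all
land near it when `misreport_frac = 0`, and only the latter should stay
there when misreporting is switched on.

## Known limitations

* Expected survival is simulation-based only; the analytic Ederer I/II and
  Hakulinen estimators are out of scope.
* No regression structure (Cox, Fine–Gray) and no Gray's test: the package
  compares marginal estimators.
* The trigam fit treats binned death counts as independent Poisson, which
  ignores the (small) multinomial dependence induced by fixed cohort size.
* Conditional survival given years already survived is not computed.
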