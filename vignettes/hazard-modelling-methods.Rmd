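---
title: "Hazard modelling on life tables: models, choices, and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hazard modelling on life tables: models, choices, and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hazglm)
```

## The modelling framework

Time-to-event data are usually analysed with the event time as the
outcome. hazglm instead discretizes follow-up into short intervals
(monthly by default) and treats the per-interval *hazard* as the outcome
of a generalized linear model. Each subject record — an outcome time in
years and a binary event indicator — is tallied into a life table: for
interval $t$, the sample size entering $n_t$, events $y_t$, censorings
$c_t$, at-risk exposure $\tau_t$, and the empirical hazard $\lambda_t =
y_t/\tau_t$. Censoring stops being a property of the outcome and becomes
a property of the exposure: a subject censored during an interval
contributes half an interval of time at risk, so

$$\tau_t = n_t - c_t/2.$$

Events contribute their full interval: an event ends the subject's
follow-up but the subject was at risk for the whole interval in the
discrete-hazard sense (the event probability is conditioned on entering
the interval). Intervals are half-open $[\mathrm{start},
\mathrm{end})$; a time falling exactly on a boundary opens the later
interval. When a data split censors everyone at a cutoff that coincides
with an interval boundary, those subjects exit *at* the boundary, so the
training life table ends there rather than opening a new interval
containing only boundary censorings (`training_lifetable()`).

With the life table in hand, interval counts are modelled as

$$y_t \sim \mathrm{Poisson}(\mu_t \tau_t), \qquad
  \mu_t = \exp(x_t^\top \beta),$$

with $\log \tau_t$ entering as an offset, so $\hat\lambda(t) =
\exp(x_t^\top\beta)$ is a per-interval (monthly) hazard. The time
covariate is evaluated at the interval midpoint in years — the midpoint
avoids $\log 0$ in the first interval and is symmetric; no other
evaluation point has a stronger claim. The choice of covariate
transform reproduces the standard survival families: no covariate gives
the exponential model, time the Gompertz, log time the Weibull. The
log-logistic and lognormal arrive through a second pathway, modelling
*cumulative* failure among the initial cohort as binomial with a
logistic or inverse-probit response of log time. Because cumulative
counts among a censored cohort are not directly observed, the binomial
response is the actuarial (life-table) cumulative failure estimate with
$n = \tau_1$ trials; this pathway is reported on its own likelihood
scale and never mixed into the Poisson comparison table.

### One likelihood scale for the comparison suite

A comparison table is only meaningful if every log-likelihood refers to
the same data representation. The suite therefore fits *all* families —
including lognormal and log-logistic, and the gamma, generalized gamma,
and generalized F which have no GLM form — by plugging the family's
hazard function $h(t;\theta)$ (from flexsurv) into the same grouped
Poisson likelihood, with $\lambda_t = h(t_{mid};\theta)\,\Delta$ and
$\Delta$ the interval width. Optimization is quasi-Newton on
unconstrained transformed parameters (log for positive parameters),
with data-driven starting values; the generalized F starts from the
fitted generalized gamma at its $P \to 0$ boundary so the nesting
$\log L_{genF} \ge \log L_{gengamma}$ is respected in practice.

## Flexible designs

**Fractional polynomials.** The log hazard is $\beta_0 + \sum_j \beta_j
x^{p_j}$ with powers from the conventional set
$\{-2,-1,-0.5,0,0.5,1,2,3\}$, power 0 encoding $\log x$ and a repeated
power $p$ encoding $(x^p, x^p\log x)$. The covariate is time in years:
fractional powers of $\log t$ would be undefined below one year, so the
log transform is available only through the 0 power. Within each order
the powers minimizing AIC are chosen; the order is then fixed by a
closed test: best second-order FP against the constant model (4 df,
each power counting 2 df for the power choice plus its coefficient),
then against the straight line (3 df), then against the best
first-order FP (2 df), by chi-square deviance tests at level
$\alpha = 0.05$, stopping at the first non-rejection. AIC ties break
toward the simpler model.

**Restricted cubic splines.** The log hazard is a natural cubic spline
of log time, built by the truncated-power construction (basis $x$ and
$N_j(x) = d_j(x) - d_{K-1}(x)$ with $d_j(x) = [(x-t_j)_+^3 -
(x-t_K)_+^3]/(t_K-t_j)$), which is exactly linear beyond the boundary
knots — extrapolations continue the last log-log slope rather than a
cubic. Internal knots sit at equally spaced percentiles of the observed
uncensored event times, boundary knots at the extreme event times; 1–5
internal knots are compared by AIC. The hand-rolled basis spans the
same space as `splines::ns`, and the test suite checks the two produce
identical fits.

**Penalized GAM.** The same natural-spline basis with dimension $q$
(intercept included; $q-2$ internal knots), with the quadratic penalty
$\rho \int f''(x)^2\,dx$ on the log hazard. The penalty matrix is exact
up to quadrature of piecewise-linear second-derivative products on a
fine grid. Fitting is penalized IRLS; model complexity is the effective
degrees of freedom $\mathrm{edf} = \mathrm{tr}[(X^\top WX + \rho
S)^{-1} X^\top WX]$, which replaces $k$ in the AIC. The smoothing
parameter minimizes that AIC by a coarse grid over $\log \rho \in
[-12, 16]$ followed by golden-section refinement; the grid stage guards
against the mild multimodality the AIC curve can show. Two variants
mirror common practice: fixed $q = 11$, and $q$ itself selected by AIC
(range 3–12). As $\rho \to \infty$ the fit collapses to the penalty's
null space — a straight line in log time, i.e. the Weibull GLM — and at
$\rho = 0$ it equals the unpenalized spline GLM; both limits are
exercised in the tests.

## Interval frailty

Unexplained interval-to-interval variation is modelled by an
independent Gaussian random intercept per interval, $b_t \sim N(0,
\psi^2)$, added to any fixed-effects design. Independence across
intervals is the minimal reading of a per-interval effect; users should
note that correlated alternatives (e.g. an autoregressive $b_t$) would
borrow more strength but are not implemented. Because the effects are
independent the marginal likelihood factorizes into one-dimensional
integrals; each is evaluated by a Laplace approximation at the interval
mode (damped Newton), and an adaptive Gauss–Hermite version of the same
integrand is kept as an independent numerical cross-check (they agree
to $10^{-4}$ on high-information instances; with sparse counts the
Laplace error is visible but small relative to the likelihood scale).
$\psi^2$ is optimized on the log-$\psi$ scale within $[e^{-16},
e^{6}]$; estimates at the lower bound are reported as a boundary fit
($\psi^2 = 0$), not an error. The parameter count adds one for
$\psi^2$. Extrapolation uses the fixed effects only: $b_t$ exists only
on observed intervals, so the predicted hazard beyond the data carries
no frailty adjustment.

## Dynamic survival models

Three state-space structures let the log hazard evolve over time: a
local level (random-walk log hazard), a local level with a fixed global
drift, and a local trend in which level and slope both receive
innovations. Filtering uses the conjugate-gamma update for log-link
Poisson counts: the state prior's mean and variance for the log hazard
are moment-matched to a gamma distribution on the hazard scale
(digamma/trigamma moments, with the trigamma inversion done by Newton
on the log scale), updated in closed form to $\mathrm{Gamma}(\alpha +
y_t, \gamma + \tau_t)$, and folded back into the state by linear Bayes.
This update is exact for the one-dimensional local level and is
standard practice for count DGLMs; it is stable at $y_t = 0$, which
matters because late life-table intervals are mostly empty.
Innovations enter by discounting: the evolved state covariance is
divided by $\delta \in [0.8, 1]$ (level block only when the drift is
fixed). At $\delta = 1$ the filter reproduces the static intercept-only
MLE exactly up to the diffuse-prior contribution.

Hyperparameters — the initial level (and drift), initial variance(s),
and $\delta$ — are chosen to minimize the one-step-ahead forecast SSE
$\sum_t (\hat\lambda_{t|t-1} - \lambda_t)^2$, giving 3, 4, and 5
parameters for the three structures. The AIC column uses the one-step
predictive log-likelihood (the sum of log negative-binomial predictive
masses of the observed counts) with that parameter count. A filtered
plug-in likelihood is also stored on the fit object; it is always
higher, and the gap is a useful overfitting diagnostic. Zero-exposure
intervals are skipped (state propagates, no update) and recorded.
Extrapolation is structure-forced: flat at the last level, or
log-linear with the drift/trend state.

## Model comparison and extrapolation scoring

`compare_models()` fits each registered model twice: on the full data
(log-likelihood, AIC, life expectancy) and on a training split censored
at 3 years (training AIC), then scores the training fit's hazard
predictions against the *full-data* empirical hazard over a holdout
window (months 37–88 by default — the split affects fitting only, never
the observed hazard). `extrapolation_sse()` returns the raw sum of
squared errors; the comparison table also reports the per-month mean
$\times 10^4$, which is the scale on which such tables are conventionally
read — over a 52-month window the raw sum is dominated by the handful of
late intervals whose at-risk denominators fall below a few subjects and
whose empirical hazards are essentially noise (values up to 0.1 on a
baseline of 0.01).

Life expectancy integrates the extrapolated survival curve
actuarially: monthly hazards clamped to $[0,1]$, $S(t) = \prod_{u\le
t}(1-\hat\lambda_u)$, $\mathrm{LE} = \Delta \sum_t S(t)$ from time zero
to a 100-year horizon. Both the horizon and the integrator matter for
heavy-tailed fits and are deliberately explicit arguments; the
integrator reproduces direct numerical integration of flexsurv survival
functions to within discretization error. No external
(general-population) constraint is applied; comparing the estimates
against such benchmarks is left to the analyst.

## The synthetic cohort generator

`simulate_tte()` draws event times by inverting the cumulative hazard
at unit-exponential deviates — closed forms for the constant, Weibull,
Gompertz, lognormal, and piecewise-constant families — and censors by an
independent administrative and/or uniform mechanism. Event and
censoring draws use partitioned RNG streams (seed and seed + 1), so
changing the censoring scheme leaves the event times of still-observed
subjects untouched. `gbsg_like()` emulates the structure of the German
Breast Cancer Study Group cohort used throughout the documentation: 686
subjects, lognormal event times with meanlog 1.53 and sdlog 1.12 (the
values the lognormal hazard fit recovers on the real cohort, giving a
unimodal hazard peaking just above 2 years), and uniform censoring over
3–7.3 years, yielding roughly 45–55% events. What the generator does
*not* emulate: covariate-driven heterogeneity, recurrent events,
informative censoring, and the exact event fraction of the real cohort
(44%); passing tests on this generator therefore demonstrate correct
recovery of known hazard structure under independent censoring, not
robustness to those features.

## Numerical choices and degenerate inputs

* GLM fits use IRLS with tolerance $10^{-12}$; intercept-only fits
  reproduce the closed form $\sum y/\sum\tau$ to near machine
  precision.
* Zero-exposure intervals carry no information and are dropped from
  likelihoods (they are kept in the life table itself; the empirical
  hazard there is reported as 0, matching the convention that
  $\lambda_t = 0$ when $\tau_t = 0$ or $y_t = 0$).
* Parametric-hazard optimization floors the Poisson mean at
  $10^{-300}$ to survive transient underflow during line search.
* Rank-deficient designs and non-convergent fits raise errors rather
  than returning silently degraded results; in `compare_models()` such
  failures are captured per row.
* AIC ties (to 10 decimals) break toward the simpler model.

## Problem sizes used in the test suite

Parameter-recovery checks use cohorts of 10,000 subjects; the
closed-test level check uses 500 replicates of 686-subject cohorts;
large-sample distributional identities use 50,000–100,000 draws. These
sizes put Monte-Carlo error comfortably below the tested tolerances
while keeping the default suite around a minute of CPU.

## Known limitations

* Only time enters the linear predictor: no treatment or prognostic
  covariates, no left truncation, competing risks, or interval-censored
  input.
* The binomial cumulative-failure pathway's handling of censoring (the
  actuarial effective denominator) is a modelling convention, not an
  exact likelihood; its fits are reported separately for this reason.
* DSM extrapolations use the final state only (no backward smoothing),
  and the predictive likelihood depends on the diffuse initial
  conditions in the first few intervals.
* Frailty predictions do not enter extrapolations (see above).
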