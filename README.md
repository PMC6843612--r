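# hazglm

Flexible parametric modelling and extrapolation of hazard functions
from time-to-event data, within the generalized linear model framework
and its extensions.

## Who this is for

Analysts who need lifetime extrapolations from censored time-to-event
data — the routine situation in health technology assessment, where
mean survival over a lifetime horizon must be estimated from a trial
with a few years of follow-up. Standard parametric survival models
(exponential, Weibull, Gompertz, log-logistic, lognormal) impose
linearity on a transformed hazard and can misrepresent hazards that
rise to a peak and decline. hazglm provides those standard models *and*
a richer family on the same footing, with a common workflow for
comparing their in-sample fit and extrapolation performance.

## The framework

Individual records (outcome time in years, event indicator) are
restructured into a **life table**: counts of events `y_t` and
censorings `c_t` per interval (monthly by default), with actuarially
adjusted at-risk exposure

```
tau_t = n_t - c_t / 2
```

(censored subjects contribute half an interval, events a full one).
Interval counts are then modelled as Poisson with the exposure as an
offset:

```
y_t ~ Poisson(mu_t * tau_t),    mu_t = exp(x_t' beta)
```

so the fitted `exp(x_t' beta)` is the per-month hazard, and the choice
of time covariate reproduces the standard models (none = exponential,
`t` = Gompertz, `log t` = Weibull; cumulative-failure binomial GLMs
give the log-logistic and lognormal). On top of this the package
implements:

* **richer parametric hazards** (gamma, lognormal, log-logistic,
  generalized gamma, generalized F) fitted on the same grouped Poisson
  likelihood, so all models are comparable by AIC (`-2 logL + 2k`);
* **fractional polynomials** with closed-test order selection;
* **restricted cubic splines** of log time with percentile knots and
  AIC knot selection;
* **penalized GAM hazards** with effective degrees of freedom as the
  parameter count;
* **interval-level Gaussian frailty** (GLMM) on any design;
* **dynamic survival models** (Poisson state-space: local level, level
  with drift, local trend), fitted by minimizing one-step-ahead
  forecast error;
* **model comparison**: AIC on full data and on a 3-year training
  split, extrapolation error against the observed hazard over a
  holdout window, and life expectancy by actuarial integration of the
  extrapolated survival curve;
* a **seeded simulator** of time-to-event cohorts with known hazard
  structure (constant, Weibull, Gompertz, unimodal lognormal,
  piecewise) and censoring.

## Worked example

```r
library(hazglm)

records <- gbsg_like(seed = 1)        # 686-subject synthetic cohort,
lt <- build_lifetable(records)        # unimodal hazard, censoring 3-7.3 y
lt
#> Life table: 88 intervals of width 0.08333 years, 686 subjects, 346 events
#>  interval   start     end   n events censorings at_risk   hazard
#>         1 0.00000 0.08333 686      0          0     686 0.000000
#>         2 0.08333 0.16667 686      0          0     686 0.000000
#>         3 0.16667 0.25000 686      5          0     686 0.007289
#>  ...

fit_parametric_hazard(lt, "lognormal")
#> <hazard_fit> lognormal (parametric_hazard)
#>   logL = -150.6570, k = 2, AIC = 305.3141
#> meanlog   sdlog
#> 1.60063 1.16341
```

The fitted coefficients recover the generating lognormal (meanlog 1.53,
sdlog 1.12) within sampling error; `logL` is the grouped monthly
Poisson likelihood and `AIC = -2 logL + 2k`.

```r
compare_models(records, list(
  "Weibull"     = function(lt, records) fit_standard(lt, "weibull"),
  "Lognormal"   = function(lt, records) fit_parametric_hazard(lt, "lognormal"),
  "RCS"         = function(lt, records) select_rcs(lt, records$time[records$event == 1]),
  "Local level" = function(lt, records) fit_dsm(lt, "local_level")))
#> Model comparison (split at 3 y, window intervals 37-88, horizon 100 y)
#>        model   logL k aic_full aic_train      sse sse_per_month_e4
#>    Lognormal -150.7 2    305.3     149.5 0.005849            1.125
#>          RCS -151.6 3    309.3     153.3 0.005951            1.144
#>      Weibull -160.1 2    324.3     156.8 0.011435            2.199
#>  Local level -163.3 3    332.6     166.0 0.006361            1.223
#>  life_expectancy
#>            9.380
#>            9.525
#>            6.103
#>            7.540
```

Each row reports the full-data log-likelihood and AIC, the AIC of a
refit on the first 3 years, the extrapolation error of that training
fit against the observed monthly hazard over months 37–88 (`sse` is the
raw sum of squared errors; `sse_per_month_e4` the per-month mean ×10⁴),
and life expectancy in years from actuarial integration of the
extrapolated hazard to 100 years. Here the unimodal truth rewards the
lognormal over the monotone-hazard Weibull on every column.
`casestudy_registry()` returns the full eleven-model suite (three DSMs,
two GAMs, RCS, FP with and without frailty, generalized gamma,
generalized F, lognormal).

A command-line interface wrapping the same functions is installed at
`inst/cli/hazglm`:

```sh
Rscript inst/cli/hazglm simulate --scenario gbsg-casestudy --seed 1 --output records.csv
Rscript inst/cli/hazglm lifetable --input records.csv --output lifetable.csv
Rscript inst/cli/hazglm compare --input records.csv --models casestudy --output-dir results/
```

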