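test_that("poisson life-table log-likelihood matches direct evaluation", {
  expect_equal(poisson_loglik(0, 0.01, 100), -1)
  expect_equal(poisson_loglik(1, 0.01, 100), -1)
  set.seed(42)
  for (i in 1:5) {
    y <- rpois(8, 3)
    lam <- runif(8, 0.01, 0.2)
    tau <- runif(8, 10, 100)
    brute <- sum(sapply(seq_along(y), function(t)
      stats::dpois(y[t], lam[t] * tau[t], log = TRUE)))
    expect_equal(poisson_loglik(y, lam, tau), brute)
  }
  expect_error(poisson_loglik(2, 0, 10), "domain error")
})

test_that("binomial cumulative log-likelihood matches the closed form", {
  expect_equal(binomial_loglik(1, 0.5, 2), log(2 * 0.25))
  # y = n with pi -> 1: approaches 0 from below
  expect_lt(binomial_loglik(3, 1 - 1e-9, 3), 0)
  expect_gt(binomial_loglik(3, 1 - 1e-9, 3), -1e-6)
  set.seed(7)
  for (i in 1:5) {
    n <- sample(3:12, 6, replace = TRUE)
    y <- rbinom(6, n, 0.4)
    p <- runif(6, 0.05, 0.95)
    brute <- sum(stats::dbinom(y, n, p, log = TRUE))
    expect_equal(binomial_loglik(y, p, n), brute)
  }
  expect_error(binomial_loglik(2, 1.2, 5), "domain error")
})

test_that("standard models map to their GLM components", {
  w <- standard_spec("weibull")
  expect_equal(w$family$distribution, "poisson")
  expect_equal(w$family$response, "exponential")
  expect_equal(w$design$transform, "log_time")
  ln <- standard_spec("lognormal")
  expect_equal(ln$family$distribution, "binomial")
  expect_equal(ln$family$response, "inverse-probit")
  expect_equal(ln$design$transform, "log_time")
  ex <- standard_spec("exponential")
  expect_equal(ex$design$transform, "none")
  gp <- standard_spec("gompertz")
  expect_equal(gp$design$transform, "time")
  ll <- standard_spec("log-logistic")
  expect_equal(ll$family$response, "logistic")
  expect_error(standard_spec("cauchy"), "valid names")
})

test_that("intercept-only Poisson fit recovers the closed-form MLE", {
  lt <- build_lifetable(constant_cohort(seed = 2, n = 500))
  fit <- fit_standard(lt, "exponential")
  expect_equal(unname(exp(fit$coefficients[1])),
               sum(lt$events) / sum(lt$at_risk), tolerance = 1e-12)
  # score equation: fitted total events reproduce observed total
  tmid <- lt_midpoints(lt)
  expect_equal(sum(predict_hazard(fit, tmid) * lt$at_risk), sum(lt$events))
})

test_that("IRLS agrees with direct numerical likelihood maximization", {
  lt <- build_lifetable(constant_cohort(seed = 4, n = 400))
  fit <- fit_standard(lt, "weibull")
  keep <- lt$at_risk > 0
  tmid <- lt_midpoints(lt)[keep]
  nll <- function(b) -poisson_loglik(lt$events[keep],
                                     pmax(exp(b[1] + b[2] * log(tmid)),
                                          1e-300),
                                     lt$at_risk[keep])
  opt <- optim(c(-3, 0), nll, method = "BFGS",
               control = list(reltol = 1e-14))
  expect_equal(fit$logL, -opt$value, tolerance = 1e-6)
})

test_that("adding a covariate never decreases the log-likelihood", {
  for (seed in c(3, 9)) {
    lt <- build_lifetable(constant_cohort(seed = seed, n = 300))
    l0 <- fit_standard(lt, "exponential")$logL
    expect_gte(fit_standard(lt, "weibull")$logL, l0 - 1e-9)
    expect_gte(fit_standard(lt, "gompertz")$logL, l0 - 1e-9)
  }
})

test_that("AIC identity holds for every emitted fit", {
  expect_equal(aic(0, 0), 0)
  expect_equal(aic(-100, 2), 204)
  lt <- build_lifetable(gbsg_like(seed = 3))
  evt <- gbsg_like(seed = 3)$time[gbsg_like(seed = 3)$event == 1]
  fits <- list(fit_standard(lt, "weibull"),
               fit_parametric_hazard(lt, "lognormal"),
               fit_fp(lt, c(0.5, 0.5)),
               fit_gam(lt, evt, q = 6))
  for (f in fits) expect_equal(f$aic, -2 * f$logL + 2 * f$k)
})

test_that("hazard predictions follow the model structure", {
  lt <- build_lifetable(constant_cohort(seed = 6, n = 400))
  tmid <- lt_midpoints(lt)
  ex <- fit_standard(lt, "exponential")
  expect_equal(diff(range(predict_hazard(ex, tmid))), 0)
  # Gompertz: log-hazard exactly linear in t (vanishing second differences)
  gp <- fit_standard(lt, "gompertz")
  lh <- log(predict_hazard(gp, seq(0.5, 5, by = 0.25)))
  expect_lt(max(abs(diff(diff(lh)))), 1e-10)
  expect_error(predict_hazard(fit_standard(lt, "weibull"), 0),
               "domain error")
})

test_that("weibull GLM slope recovers shape - 1 on simulated data", {
  shape <- 1.6
  rec <- simulate_tte(tte_scenario("weibull",
                                   list(shape = shape, scale = 4),
                                   n = 10000, seed = 31, admin_censor = 8))
  fit <- fit_standard(build_lifetable(rec), "weibull")
  expect_equal(unname(fit$coefficients[2]), shape - 1, tolerance = 0.08)
})

test_that("binomial pathway fits cumulative failure and derives hazards", {
  rec <- simulate_tte(tte_scenario("lognormal",
                                   list(meanlog = 1.2, sdlog = 0.9),
                                   n = 4000, seed = 13, admin_censor = 10))
  lt <- build_lifetable(rec)
  fit <- fit_standard(lt, "lognormal")
  # probit slope/intercept recover (meanlog, sdlog)
  sigma <- 1 / fit$coefficients[2]
  mu <- -fit$coefficients[1] / fit$coefficients[2]
  expect_equal(unname(mu), 1.2, tolerance = 0.1)
  expect_equal(unname(sigma), 0.9, tolerance = 0.1)
  h <- predict_hazard(fit, lt_midpoints(lt))
  expect_true(all(h >= 0))
  expect_equal(fit$k, 2)
})
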