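test_that("discount 1 reduces the filter to the static constant-rate MLE", {
  lt <- build_lifetable(constant_cohort(rate = 0.25, n = 800, seed = 2))
  spec <- dsm_spec("local_level", b0 = log(0.02), Z0 = 25, delta = 1)
  fit <- dsm_filter(lt, spec)
  final <- unname(fit$final_gamma["alpha"] / fit$final_gamma["gamma"])
  expect_lt(abs(final - sum(lt$events) / sum(lt$at_risk)), 1e-4)
})

test_that("forecasts are causal: later data never move earlier forecasts", {
  lt <- build_lifetable(constant_cohort(n = 400, seed = 3))
  spec <- dsm_spec("local_level", b0 = -3, Z0 = 4, delta = 0.9)
  f1 <- dsm_filter(lt, spec)
  lt2 <- lt
  tpert <- 30
  lt2$events[tpert] <- lt2$events[tpert] + 5
  lt2$hazard <- ifelse(lt2$at_risk > 0, lt2$events / lt2$at_risk, 0)
  f2 <- dsm_filter(lt2, spec)
  expect_equal(f1$forecasts[1:tpert], f2$forecasts[1:tpert])
  expect_false(isTRUE(all.equal(f1$forecasts[tpert + 1],
                                f2$forecasts[tpert + 1])))
})

test_that("a zero-event life table shrinks the forecasts toward zero", {
  width <- 1 / 12
  N <- 40
  lt <- structure(data.frame(interval = 1:N, start = (0:(N - 1)) * width,
                             end = (1:N) * width, n = 500, events = 0,
                             censorings = 0, at_risk = 500, hazard = 0),
                  class = c("lifetable", "data.frame"), width = width)
  fit <- dsm_filter(lt, dsm_spec("local_level", b0 = log(0.05), Z0 = 1,
                                 delta = 0.95))
  fc <- fit$forecasts
  expect_true(all(diff(fc) < 0))
  expect_lt(fc[N], fc[1] / 5)
})

test_that("the filter tracks a hazard jump that defeats the static fit", {
  rates <- c(0.1, 0.6)
  rec <- simulate_tte(tte_scenario("piecewise",
                                   list(rates = rates, breaks = 2),
                                   n = 20000, seed = 9, admin_censor = 4))
  lt <- build_lifetable(rec)
  fit <- dsm_filter(lt, dsm_spec("local_level", b0 = log(0.01), Z0 = 1,
                                 delta = 0.85))
  static <- fit_standard(lt, "exponential")
  post <- lt$interval[lt$start > 2.5]  # past the jump, past the filter lag
  truth <- rates[2] / 12
  dyn_err <- mean(abs(fit$forecasts[post] - truth))
  stat_err <- mean(abs(predict_hazard(static, lt_midpoints(lt))[post] - truth))
  expect_lt(dyn_err, stat_err)
})

test_that("gamma moment matching agrees with grid integration", {
  # the conjugate update's predictive mean and posterior moments, checked
  # against brute-force quadrature over the hazard scale
  f <- -3.2; q <- 0.4
  alpha <- hazglm:::trigamma_inv(q)
  gam <- exp(digamma(alpha) - f)
  mu <- seq(1e-6, 2, length.out = 400000)
  dens <- stats::dgamma(mu, alpha, gam)
  dens <- dens / sum(dens)
  expect_equal(sum(mu * dens), alpha / gam, tolerance = 1e-3)
  expect_equal(sum(log(mu) * dens), f, tolerance = 1e-3)
  expect_equal(sum((log(mu) - f)^2 * dens), q, tolerance = 1e-2)
  # posterior after observing y events with exposure tau
  y <- 4; tau <- 300
  post <- dens * stats::dpois(y, mu * tau)
  post <- post / sum(post)
  expect_equal(sum(mu * post), (alpha + y) / (gam + tau), tolerance = 1e-3)
})

test_that("hyperparameter search matches the structures' parameter counts", {
  lt <- build_lifetable(gbsg_like(seed = 1))
  ll <- fit_dsm(lt, "local_level")
  expect_equal(ll$k, 3)
  expect_equal(ll$aic, -2 * ll$pred_logL + 2 * 3)
  ld <- fit_dsm(lt, "level_with_drift")
  expect_equal(ld$k, 4)
  tr <- fit_dsm(lt, "local_trend")
  expect_equal(tr$k, 5)
})

test_that("a constant hazard drives the discount toward one", {
  lt <- build_lifetable(constant_cohort(rate = 0.3, n = 4000, seed = 4))
  fit <- fit_dsm(lt, "local_level")
  expect_gt(fit$spec$delta, 0.95)
})

test_that("a rising hazard yields a positive fitted drift", {
  rec <- simulate_tte(tte_scenario("gompertz", list(a = 0.05, b = 0.6),
                                   n = 8000, seed = 6, admin_censor = 5))
  lt <- build_lifetable(rec)
  fit <- fit_dsm(lt, "level_with_drift")
  expect_gt(fit$spec$drift, 0)
})

test_that("extrapolation shape is forced by the structure", {
  lt <- build_lifetable(gbsg_like(seed = 2))
  ll <- fit_dsm(lt, "local_level")
  fc <- dsm_forecast(ll, 24)
  expect_equal(diff(range(fc)), 0)
  expect_true(all(fc > 0))
  # positive drift: strictly increasing extrapolation
  spec <- dsm_spec("level_with_drift", b0 = -4, drift = 0.02, Z0 = 1,
                   delta = 0.95)
  fit <- dsm_filter(lt, spec)
  fit$k <- 4
  expect_gt(fit$final_mean[2], 0)
  expect_true(all(diff(dsm_forecast(fit, 24)) > 0))
  # zero-trend two-state forecast equals the flat forecast from its state
  fit0 <- dsm_filter(lt, dsm_spec("level_with_drift", b0 = -4, drift = 0,
                                  Z0 = 1, delta = 1))
  expect_equal(dsm_forecast(fit0, 12),
               rep(exp(fit0$final_mean[1]), 12), tolerance = 1e-12)
  expect_error(dsm_forecast(ll, 0), "horizon")
})
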