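const_model <- function(level) {
  structure(list(name = "const", kind = "stub", coefficients = log(level),
                 logL = 0, k = 1, aic = 2,
                 predict_hazard = function(times) rep(level, length(times))),
            class = "hazard_fit")
}

test_that("extrapolation error matches its closed forms", {
  lt <- build_lifetable(constant_cohort(n = 500, seed = 8))
  w <- 10:30
  # perfect forecast: zero error
  obs_model <- structure(list(predict_hazard = function(times) {
    lt$hazard[round(times / lt_width(lt) + 0.5)]
  }), class = "hazard_fit")
  expect_equal(extrapolation_sse(obs_model, lt, w), 0)
  # constant offset epsilon over m intervals: m * epsilon^2
  eps <- 0.003
  off_model <- structure(list(predict_hazard = function(times) {
    lt$hazard[round(times / lt_width(lt) + 0.5)] + eps
  }), class = "hazard_fit")
  expect_equal(extrapolation_sse(off_model, lt, w), length(w) * eps^2)
  # random predictions: brute-force summation
  set.seed(2)
  pred <- runif(length(w), 0, 0.05)
  rnd_model <- structure(list(predict_hazard = function(times) pred),
                         class = "hazard_fit")
  expect_equal(extrapolation_sse(rnd_model, lt, w),
               sum((pred - lt$hazard[w])^2))
  expect_equal(extrapolation_sse(rnd_model, lt, w, average = TRUE),
               sum((pred - lt$hazard[w])^2) / length(w))
  expect_error(extrapolation_sse(rnd_model, lt, 1:500), "window")
})

test_that("extrapolation error is additive over a window partition", {
  lt <- build_lifetable(constant_cohort(n = 500, seed = 8))
  m <- const_model(0.012)
  expect_equal(extrapolation_sse(m, lt, 5:40),
               extrapolation_sse(m, lt, 5:20) +
                 extrapolation_sse(m, lt, 21:40))
})

test_that("life expectancy matches geometric and degenerate closed forms", {
  lam <- 0.02
  le <- life_expectancy(const_model(lam), horizon = 400)
  expect_equal(le, (1 / 12) * (1 - lam) / lam, tolerance = 1e-6)
  expect_equal(life_expectancy(const_model(0), horizon = 50), 50)
  expect_lt(life_expectancy(const_model(1), horizon = 50), 0.1)
  # pointwise-higher hazard never lengthens life
  expect_lt(life_expectancy(const_model(0.03)),
            life_expectancy(const_model(0.02)))
})

test_that("model comparison recovers simulation truth for the exponential", {
  rate <- 0.25
  rec <- simulate_tte(tte_scenario("constant", list(rate = rate), n = 8000,
                                   seed = 15, admin_censor = 7.3))
  reg <- list(exponential = function(lt, records)
    fit_standard(lt, "exponential"))
  tab <- compare_models(rec, reg, split_cutoff = 3, window = 37:80,
                        horizon = 200)
  expect_equal(nrow(tab), 1L)
  expect_lt(tab$sse_per_month_e4, 2)
  expect_equal(tab$life_expectancy, 1 / rate, tolerance = 0.05)
  expect_true(is.na(tab$error))
})

test_that("identical registry entries give identical rows", {
  rec <- gbsg_like(seed = 4)
  reg <- list(a = function(lt, records) fit_standard(lt, "weibull"),
              b = function(lt, records) fit_standard(lt, "weibull"))
  tab <- compare_models(rec, reg)
  cols <- setdiff(names(tab), c("model", "error"))
  expect_equal(as.numeric(tab[1, cols]), as.numeric(tab[2, cols]))
})

test_that("a late split cutoff makes training and full AICs coincide", {
  rec <- gbsg_like(seed = 5)
  reg <- list(weibull = function(lt, records) fit_standard(lt, "weibull"))
  tab <- compare_models(rec, reg, split_cutoff = 10, window = 30:60)
  expect_equal(tab$aic_train, tab$aic_full, tolerance = 1e-8)
})

test_that("model failures are recorded in-row, not fatal", {
  rec <- gbsg_like(seed = 6)
  reg <- list(ok = function(lt, records) fit_standard(lt, "exponential"),
              broken = function(lt, records) stop("deliberate failure"))
  tab <- compare_models(rec, reg)
  expect_equal(nrow(tab), 2L)
  expect_true("deliberate failure" %in% tab$error)
  expect_true(any(is.finite(tab$aic_full)))
})

test_that("hazard curves carry observed, fitted, and extrapolated layers", {
  rec <- gbsg_like(seed = 7)
  lt <- build_lifetable(rec)
  fits <- list(weibull = fit_standard(lt, "weibull"))
  cv <- hazard_curves(fits, lt, horizon = 10)
  expect_setequal(unique(cv$type), c("observed", "fitted", "extrapolated"))
  expect_true(all(cv$hazard[cv$model == "weibull"] > 0))
})

test_that("fitted models serialize to JSON and back", {
  lt <- build_lifetable(gbsg_like(seed = 8))
  fit <- fit_fp(lt, c(0, 1))
  path <- withr::local_tempfile(fileext = ".json")
  model_to_json(fit, path)
  back <- model_from_json(path)
  expect_equal(back$fp_powers, c(0, 1))
  expect_equal(unlist(back$coefficients), fit$coefficients,
               tolerance = 1e-12)
  expect_equal(back$aic, fit$aic, tolerance = 1e-10)
})
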