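#' Extrapolation error over a holdout window
#'
#' Sum (or per-interval mean) of squared differences between
#' model-predicted and observed empirical per-interval hazards over a window
#' of life-table intervals.
#'
#' @param model a fitted model (\code{hazard_fit} or \code{dsm_fit}).
#' @param lt the observed \code{lifetable} providing the empirical hazards.
#' @param window integer interval indices (1-based; default months 37-88).
#' @param average if TRUE return the per-interval mean instead of the sum.
#' @return a nonnegative scalar.
#' @export
extrapolation_sse <- function(model, lt, window = 37:88, average = FALSE) {
  stopifnot(inherits(lt, "lifetable"))
  if (any(window < 1) || any(window > nrow(lt)))
    stop("validation error: window outside the observed life table")
  tmid <- lt_midpoints(lt)[window]
  pred <- predict_hazard(model, tmid)
  obs <- lt$hazard[window]
  err <- sum((pred - obs)^2)
  if (average) err / length(window) else err
}

#' Mean life expectancy from an extrapolated hazard
#'
#' Actuarial integration: per-interval hazards \eqn{\hat\lambda_u} (clamped
#' to [0, 1]) give survival \eqn{S(t) = \prod_{u \le t} (1 -
#' \hat\lambda_u)}, and mean survival is \eqn{\Delta \sum_t S(t)} over
#' intervals up to the horizon.
#'
#' @param model a fitted model.
#' @param horizon horizon in years (default 100).
#' @param width interval width in years (default monthly).
#' @return life expectancy in years.
#' @export
life_expectancy <- function(model, horizon = 100, width = 1 / 12) {
  stopifnot(horizon > 0)
  H <- ceiling(horizon / width)
  tmid <- (seq_len(H) - 0.5) * width
  lam <- predict_hazard(model, tmid)
  if (any(!is.finite(lam)) || any(lam < 0))
    stop("validation error: hazard predictions must be finite and nonnegative")
  lam <- pmin(lam, 1)
  S <- cumprod(1 - lam)
  width * sum(S)
}

#' Model registry for the breast-cancer case-study suite
#'
#' The eleven-model comparison suite: three dynamic survival models, two
#' GAMs (fixed q = 11 and AIC-selected q), the AIC-selected restricted cubic
#' spline, the closed-test fractional polynomial with and without interval
#' frailty, and the generalized gamma, generalized F, and lognormal hazards
#' fitted on the Poisson life-table likelihood.
#'
#' @return a named list of fitting functions \code{function(lt, records)}.
#' @export
casestudy_registry <- function() {
  ev <- function(records) records$time[records$event == 1]
  fp_powers <- function(lt) {
    # closed-test FP; frailty variant reuses its selected powers
    sel <- select_fp(lt)
    if (is.null(sel$details$powers)) sel$details$candidates$fp2_powers
    else sel$details$powers
  }
  list(
    "Local level" = function(lt, records) fit_dsm(lt, "local_level"),
    "Local level with drift" = function(lt, records)
      fit_dsm(lt, "level_with_drift"),
    "Local-level local trend" = function(lt, records)
      fit_dsm(lt, "local_trend"),
    "GAM v1" = function(lt, records) fit_gam(lt, ev(records), q = 11),
    "GAM v2" = function(lt, records)
      fit_gam(lt, ev(records), select_q = TRUE),
    "RCS" = function(lt, records) select_rcs(lt, ev(records)),
    "FP" = function(lt, records) select_fp(lt),
    "FP with random effects" = function(lt, records) {
      sel <- select_fp(lt)
      pw <- sel$details$powers
      if (is.null(pw)) pw <- 1
      fit_frailty(lt, pw)
    },
    "Generalized Gamma" = function(lt, records)
      fit_parametric_hazard(lt, "generalized-gamma"),
    "Generalized F" = function(lt, records)
      fit_parametric_hazard(lt, "generalized-F"),
    "Lognormal" = function(lt, records)
      fit_parametric_hazard(lt, "lognormal"))
}

#' Registry of the standard survival models
#'
#' @param pathway \code{"poisson"} fits every family on the Poisson
#'   life-table likelihood (one comparable scale); \code{"table2"} uses the
#'   GLM specifications (binomial pathway for log-logistic/lognormal).
#' @return a named list of fitting functions.
#' @export
standard_registry <- function(pathway = c("poisson", "table2")) {
  pathway <- match.arg(pathway)
  if (pathway == "poisson") {
    nms <- c("exponential", "weibull", "gamma", "log-logistic", "lognormal",
             "generalized-gamma", "generalized-F")
    fits <- lapply(nms, function(nm)
      function(lt, records) fit_parametric_hazard(lt, nm))
    names(fits) <- nms
    c(list(gompertz = function(lt, records) fit_standard(lt, "gompertz")),
      fits)
  } else {
    nms <- c("exponential", "gompertz", "weibull", "log-logistic",
             "lognormal")
    fits <- lapply(nms, function(nm)
      function(lt, records) fit_standard(lt, nm))
    names(fits) <- nms
    fits
  }
}

#' Compare hazard models by fit, extrapolation error, and life expectancy
#'
#' Each registry model is fitted on the full data (AIC, life expectancy) and
#' on a training split censored at the cutoff (training AIC); extrapolation
#' error compares the training fit's hazard predictions with the full-data
#' empirical hazard over the holdout window. Model failures are recorded
#' in-row rather than aborting the table.
#'
#' @param records a \code{subject_records} data frame.
#' @param registry named list of fitting functions \code{function(lt,
#'   records)}.
#' @param split_cutoff training cutoff in years (default 3).
#' @param window holdout interval indices (default months 37-88).
#' @param horizon life-expectancy horizon in years.
#' @param width interval width in years.
#' @return a data frame of class \code{hazard_comparison} with one row per
#'   model: \code{logL}, \code{k}, \code{aic_full}, \code{aic_train},
#'   \code{sse} (raw sum over the window), \code{sse_per_month_e4} (mean
#'   squared error \eqn{\times 10^4}, the case-study table's convention),
#'   \code{life_expectancy}, and \code{error}.
#' @export
compare_models <- function(records, registry, split_cutoff = 3,
                           window = 37:88, horizon = 100, width = 1 / 12) {
  if (!length(registry)) stop("validation error: empty model registry")
  lt_full <- build_lifetable(records, width)
  rec_train <- truncate_followup(records, split_cutoff)
  lt_train <- training_lifetable(records, split_cutoff, width)
  window <- window[window <= nrow(lt_full)]
  rows <- lapply(names(registry), function(nm) {
    f <- registry[[nm]]
    out <- data.frame(model = nm, logL = NA_real_, k = NA_real_,
                      aic_full = NA_real_, aic_train = NA_real_,
                      sse = NA_real_, sse_per_month_e4 = NA_real_,
                      life_expectancy = NA_real_, error = NA_character_,
                      stringsAsFactors = FALSE)
    full_fit <- tryCatch(f(lt_full, records), error = function(e) e)
    if (inherits(full_fit, "error")) {
      out$error <- conditionMessage(full_fit)
      return(out)
    }
    out$logL <- full_fit$logL
    out$k <- full_fit$k
    out$aic_full <- full_fit$aic
    out$life_expectancy <- tryCatch(
      life_expectancy(full_fit, horizon, width), error = function(e) NA_real_)
    train_fit <- tryCatch(f(lt_train, rec_train), error = function(e) e)
    if (inherits(train_fit, "error")) {
      out$error <- conditionMessage(train_fit)
      return(out)
    }
    out$aic_train <- train_fit$aic
    sse <- tryCatch(extrapolation_sse(train_fit, lt_full, window),
                    error = function(e) NA_real_)
    out$sse <- sse
    out$sse_per_month_e4 <- sse / length(window) * 1e4
    out
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$aic_full), ]
  rownames(tab) <- NULL
  structure(tab, class = c("hazard_comparison", "data.frame"),
            window = window, split_cutoff = split_cutoff, horizon = horizon)
}

#' @export
print.hazard_comparison <- function(x, ...) {
  cat(sprintf("Model comparison (split at %g y, window intervals %d-%d, horizon %g y)\n",
              attr(x, "split_cutoff"), min(attr(x, "window")),
              max(attr(x, "window")), attr(x, "horizon")))
  df <- as.data.frame(x)
  df$error <- NULL
  print(df, row.names = FALSE, digits = 4)
  errs <- x$error[!is.na(x$error)]
  if (length(errs)) cat("failures:", length(errs), "model(s)\n")
  invisible(x)
}

#' Tidy hazard curves for plotting
#'
#' Observed empirical hazards plus each model's fitted/extrapolated hazard
#' on a monthly grid, in long format.
#'
#' @param fits named list of fitted models.
#' @param lt observed \code{lifetable}.
#' @param horizon extrapolation horizon in years.
#' @return data frame with columns \code{model}, \code{time},
#'   \code{hazard}, \code{type} (\code{"observed"}, \code{"fitted"}, or
#'   \code{"extrapolated"}).
#' @export
hazard_curves <- function(fits, lt, horizon = 10) {
  width <- lt_width(lt)
  obs <- data.frame(model = "observed", time = lt_midpoints(lt),
                    hazard = lt$hazard, type = "observed",
                    stringsAsFactors = FALSE)
  tmax <- max(lt$end)
  H <- ceiling(horizon / width)
  grid <- (seq_len(H) - 0.5) * width
  rows <- lapply(names(fits), function(nm) {
    data.frame(model = nm, time = grid,
               hazard = predict_hazard(fits[[nm]], grid),
               type = ifelse(grid <= tmax, "fitted", "extrapolated"),
               stringsAsFactors = FALSE)
  })
  rbind(obs, do.call(rbind, rows))
}
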